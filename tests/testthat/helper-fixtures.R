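# Shared fixtures, computed lazily and cached for the whole test run.
# The benchmark catalogue (5,000 compounds, 400 analog families) is the
# generator's default; fingerprinting it once keeps the suite fast.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache, inherits = FALSE))
    assign(key, force(expr), envir = .cache)
  get(key, envir = .cache, inherits = FALSE)
}

benchmark_collection <- function() {
  cached("benchmark_collection", generate_fixture(fixture_spec(seed = 1)))
}

benchmark_fingerprints <- function() {
  cached("benchmark_fingerprints", radial_fingerprints(benchmark_collection()))
}

small_fixture <- function() {
  cached("small_fixture",
         generate_fixture(fixture_spec(n_total = 120, n_families = 12,
                                       seed = 42)))
}

small_fingerprints <- function() {
  cached("small_fingerprints", radial_fingerprints(small_fixture()))
}

# A tiny panel of well-known molecules used across oracle tests.
panel_smiles <- function() {
  c(benzene = "c1ccccc1", toluene = "Cc1ccccc1", phenol = "Oc1ccccc1",
    naphthol = "Oc1ccc2ccccc2c1", ethanol = "CCO", ethylamine = "CCN",
    butane = "CCCC", pyridine = "c1ccncc1", anisole = "COc1ccccc1",
    benzamide = "NC(=O)c1ccccc1", furan = "c1ccoc1", thiophene = "c1ccsc1",
    cyclohexane = "C1CCCCC1", morpholine = "C1COCCN1",
    indole = "c1ccc2[nH]ccc2c1", caffeine_frag = "Cn1ccnc1",
    fluorobenzene = "Fc1ccccc1", tfm_benzene = "FC(F)(F)c1ccccc1",
    acetophenone = "CC(=O)c1ccccc1", benzonitrile = "N#Cc1ccccc1")
}

# Run a short python snippet against the RDKit toolkit and return parsed
# JSON; used as the independent cross-check oracle.
rdkit_json <- function(code) {
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(code)), stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) return(NULL)
  jsonlite::fromJSON(paste(out, collapse = "\n"))
}
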