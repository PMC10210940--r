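# Shared synthetic fixtures, built once per test run.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, build(), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# default study-conditions fixture: 4 clades x 30, 60 decoys, tandem layout
default_fixture <- function() {
  memo("default", function() stcminer::make_genome(stcminer::sim_spec(seed = 20260925L)))
}

# its pipeline result (used by the filter-cascade and end-to-end checks)
default_pipeline <- function() {
  memo("default_pipeline", function() {
    fx <- default_fixture()
    stcminer::run_pipeline(fx$proteome, fx$seeds, fx$seed_clades, fx$loci)
  })
}

# small 4-clade family set without decoys (clade-assignment benchmarks)
small_families <- function(n_per_clade = 12L, seed = 7L) {
  memo(paste0("fam", n_per_clade, "_", seed), function() {
    models <- lapply(c("1", "2", "3", "4"), function(cl) {
      stcminer::make_clade_model(cl, length = 300L + as.integer(cl) * 4L,
                                 divergence = 50, seed = seed + as.integer(cl))
    })
    names(models) <- c("1", "2", "3", "4")
    fams <- lapply(names(models), function(cl) {
      stcminer::sample_family(models[[cl]], n_per_clade, penetrance = 0.9,
                              seed = seed + 10L + as.integer(cl))
    })
    refs <- lapply(names(models), function(cl) {
      r <- stcminer::sample_family(models[[cl]], 2L, penetrance = 1,
                                   seed = seed + 20L + as.integer(cl),
                                   prefix = paste0("ref", cl, "_"))
      r$division <- "other"
      r
    })
    ref_recs <- do.call(rbind, refs)
    list(models = models,
         candidates = do.call(rbind, fams),
         truth = rep(names(models), each = n_per_clade),
         references = ref_recs,
         ref_clades = setNames(rep(names(models), each = 2L), ref_recs$id))
  })
}
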