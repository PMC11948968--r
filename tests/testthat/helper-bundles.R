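# Memoized expensive fixtures shared across test files.

.bundle_cache <- new.env(parent = emptyenv())

# default-configuration bundle (seed 42), written to disk once per run
default_bundle <- function() {
  if (!exists("default", envir = .bundle_cache)) {
    cfg <- sim_config(seed = 42)
    dir <- file.path(tempdir(), "default_bundle_42")
    assign("default", simulate_bundle(cfg, dir), envir = .bundle_cache)
  }
  get("default", envir = .bundle_cache)
}

# young-subfamily configuration: one subfamily of fully identical copies
# (divergence 0) next to a mildly diverged one -- the regime in which the
# prior-free EM leaves tied best hits
young_bundle <- function() {
  if (!exists("young", envir = .bundle_cache)) {
    cfg <- sim_config(divergence = c(0, 0.02), seed = 42)
    truth <- make_te_genome(cfg)
    sim <- simulate_fragments(truth, cfg)
    aln <- synthetic_align(sim, truth)
    fm <- fragment_matrix(aln[, c("fragment_id", "locus_id", "score")],
                          truth$annotation)
    assign("young", list(truth = truth, sim = sim, fm = fm),
           envir = .bundle_cache)
  }
  get("young", envir = .bundle_cache)
}
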