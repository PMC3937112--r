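## The seven-clade synthetic benchmark, computed lazily once per test run
## and shared by the module and acceptance tests.

.bench_env <- new.env(parent = emptyenv())

bench <- function(what) {
  if (is.null(.bench_env$cfg)) {
    .bench_env$cfg <- benchmark_config(seed = 1)
    .bench_env$gen <- generate_tdna(.bench_env$cfg)
    .bench_env$parts <- partition_tdna(.bench_env$gen$dataset)
  }
  if (what == "fit" && is.null(.bench_env$fit))
    .bench_env$fit <- multiway_fit(.bench_env$parts, seed = 1)
  if (what %in% c("queries", "converged") && is.null(.bench_env$queries)) {
    cfg <- .bench_env$cfg
    qspec <- cfg$clades[["C1"]]
    qspec$name <- "Q"
    qcfg <- cfg
    qcfg$clades <- list(Q = qspec)
    qcfg$seed <- cfg$seed + 5000
    qgen <- generate_tdna(qcfg)
    .bench_env$queries <- qgen$dataset
    protect <- unique(unlist(lapply(.bench_env$gen$planted,
                                    function(p) p$pos)))
    .bench_env$converged <- converge_composition(
      qgen$dataset, unique(qgen$dataset$records$genome_id),
      at_shift = 0.5, protect = protect, seed = 11)
  }
  switch(what,
         cfg = .bench_env$cfg,
         gen = .bench_env$gen,
         parts = .bench_env$parts,
         fit = .bench_env$fit,
         queries = .bench_env$queries,
         converged = .bench_env$converged)
}
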