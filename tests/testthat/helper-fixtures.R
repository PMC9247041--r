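# Session-cached fixtures: the default simulated study is expensive, so it
# (and the per-stage results derived from it) is built once per test run.

.fx <- new.env(parent = emptyenv())

fx_sim <- function() {
  if (is.null(.fx$sim)) .fx$sim <- simulate_study(simulation_params())
  .fx$sim
}

fx_classified <- function() {
  if (is.null(.fx$classified)) {
    .fx$classified <- classify_transcripts(fx_sim()$candidates, fx_sim()$ann)
  }
  .fx$classified
}

fx_verdicts <- function() {
  if (is.null(.fx$verdicts)) {
    .fx$verdicts <- coding_verdicts(fx_sim()$cand_seqs)
  }
  .fx$verdicts
}

fx_fpkm <- function() {
  if (is.null(.fx$fpkm)) .fx$fpkm <- fpkm(fx_sim()$expr)
  .fx$fpkm
}

fx_cascade <- function() {
  if (is.null(.fx$cascade)) {
    .fx$cascade <- filter_cascade(fx_classified(), fx_verdicts(), fx_fpkm())
  }
  .fx$cascade
}

fx_dels <- function() {
  if (is.null(.fx$dels)) {
    sim <- fx_sim()
    retained <- fx_cascade()$table$transcript_id[fx_cascade()$table$stage == "retained"]
    sf <- size_factors(sim$expr)
    tests <- lapply(list(S1_S2 = c("S1", "S2"), S1_S3 = c("S1", "S3"),
                         S2_S3 = c("S2", "S3")), function(ct) {
      res <- nb_wald_test(sim$expr, ct[1L], ct[2L], sf = sf)
      res[res$feature %in% retained, ]
    })
    .fx$dels <- call_dels(tests)
  }
  .fx$dels
}

# a small, fast parameter set for structural / determinism tests
small_params <- function(seed = 7L) {
  simulation_params(
    genes_per_chrom = 30L, n_u = 16L, n_i = 5L, n_o = 5L, n_x = 5L,
    n_eq = 3L, n_short = 3L, n_mono = 3L, n_lowexpr = 3L,
    n_codinglike = 3L, n_domain = 2L,
    n_mirna_planted = 2L, n_mirna_decoy = 1L,
    n_pos_conserved = 2L, n_pos_nonconserved = 1L,
    n_inversions = 0L, n_translocations = 0L, n_random_deletions = 2L,
    rng_seed = seed
  )
}

fx_small_sim <- function() {
  if (is.null(.fx$small)) .fx$small <- simulate_study(small_params())
  .fx$small
}
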