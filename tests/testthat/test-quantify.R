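make_run <- function(run_id, construct, accession, abundance, peptides = NULL,
                     batch_id = "b1") {
  peptides <- peptides %||% ifelse(abundance > 0, 5L, 0L)
  evidence_table(
    data.frame(accession = accession, gene = paste0("G_", accession),
               unique_peptides = peptides, abundance = abundance,
               stringsAsFactors = FALSE),
    fixture_metadata(run_id = run_id, construct = construct, batch_id = batch_id)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("median-factor normalization recovers exact proportionality", {
  acc <- sprintf("P%d", 1:6)
  a <- make_run("r_a", "bait_fusion", acc, c(10, 20, 30, 40, 50, 60))
  b <- make_run("r_b", "control", acc, 2 * c(10, 20, 30, 40, 50, 60))
  q <- normalize_runs(list(a, b))
  expect_equal(unname(q$scale_factors["r_b"]), 0.5)
  expect_equal(q$abundance[, "r_a"], q$abundance[, "r_b"])

  # single shared protein
  c1 <- make_run("r_c", "bait_fusion", "P1", 10)
  c2 <- make_run("r_d", "control", c("P1", "P2"), c(40, 5))
  q2 <- normalize_runs(list(c1, c2))
  expect_equal(q2$reference_run, "r_d")  # most quantified proteins wins
  expect_equal(unname(q2$scale_factors["r_c"]), 4)
})

test_that("planted per-run scale factors are recovered to 1e-9", {
  set.seed(21)
  acc <- sprintf("P%02d", 1:30)
  base <- rlnorm(30, 12, 1)
  scales <- c(1, 0.37, 2.9, 14.2)
  runs <- lapply(seq_along(scales), function(i) {
    make_run(sprintf("r%02d", i), if (i <= 2) "bait_fusion" else "control",
             acc, base * scales[i])
  })
  q <- normalize_runs(runs)
  ref_scale <- scales[match(q$reference_run, sprintf("r%02d", 1:4))]
  expected <- ref_scale / scales
  expect_equal(unname(q$scale_factors), unname(expected), tolerance = 1e-9)
})

test_that("normalization errors when a run shares nothing with the reference", {
  a <- make_run("r_a", "bait_fusion", c("P1", "P2"), c(1, 2))
  b <- make_run("r_b", "control", c("P3", "P4"), c(1, 2))
  expect_error(normalize_runs(list(a, b)), "r_",
               class = "bioid_normalization_error")
})

test_that("ratio arithmetic matches hand-computed means", {
  runs <- list(
    make_run("b1r1", "bait_fusion", "P1", 2e6),
    make_run("b1r2", "bait_fusion", "P1", 4e6),
    make_run("c1r1", "control", "P1", 1e6),
    make_run("c1r2", "control", "P1", 1e6)
  )
  q <- normalize_runs(runs, method = "none")
  rt <- compute_ratios(q)
  expect_equal(rt$ratio, 3.0)

  # bait = control on all replicates: identity ratio
  runs2 <- list(make_run("b", "bait_fusion", c("P1", "P2"), c(5, 7)),
                make_run("c", "control", c("P1", "P2"), c(5, 7)))
  rt2 <- compute_ratios(normalize_runs(runs2, method = "none"))
  expect_equal(rt2$ratio, c(1, 1))

  # all-zero control: undefined, flagged, not an error
  runs3 <- list(make_run("b", "bait_fusion", c("P1", "P2"), c(5, 3)),
                make_run("c", "control", c("P1", "P2"), c(4, 0),
                         peptides = c(2L, 0L)))
  rt3 <- compute_ratios(normalize_runs(runs3, method = "none"))
  expect_true(is.na(rt3$ratio[rt3$accession == "P2"]))
  expect_false(rt3$ratio_defined[rt3$accession == "P2"])
})

test_that("ratios are invariant under global rescaling of the whole batch", {
  set.seed(31)
  sim <- generate_experiment(simulation_config(seed = 31, n_proteins = 40,
    class_fractions = c(bait = 1, true_interactor = 4, background = 35) / 40,
    cell_lines = "HCT116", biotin_hours = 6, treatments = "vehicle"))
  rt <- compute_ratio_table(sim)
  scaled <- lapply(sim$evidence, function(ev) {
    s <- runif(1, 0.1, 10)
    df <- as.data.frame(ev)
    df$abundance <- df$abundance * s
    evidence_table(df, attr(ev, "metadata"))
  })
  rt2 <- compute_ratio_table(scaled, sim$manifest)
  expect_equal(rt2$ratio, rt$ratio, tolerance = 1e-9)
})

test_that("swapping constructs inverts the ratio", {
  set.seed(41)
  acc <- sprintf("P%d", 1:10)
  runs <- list(
    make_run("b1", "bait_fusion", acc, rlnorm(10, 10, 0.5)),
    make_run("b2", "bait_fusion", acc, rlnorm(10, 10, 0.5)),
    make_run("c1", "control", acc, rlnorm(10, 10, 0.5)),
    make_run("c2", "control", acc, rlnorm(10, 10, 0.5))
  )
  q <- normalize_runs(runs, method = "none")
  fwd <- compute_ratios(q)
  swapped <- lapply(runs, function(ev) {
    md <- attr(ev, "metadata")
    md$construct <- if (md$construct == "bait_fusion") "control" else "bait_fusion"
    evidence_table(as.data.frame(ev), md)
  })
  rev <- compute_ratios(normalize_runs(swapped, method = "none"))
  expect_equal(fwd$ratio * rev$ratio, rep(1, 10), tolerance = 1e-12)
})

test_that("observed interactor ratios track planted effects across a range", {
  effects <- c(1.5, 2, 3, 5, 8)
  observed <- vapply(seq_along(effects), function(i) {
    cfg <- simulation_config(seed = 50 + i, n_proteins = 20,
      class_fractions = c(bait = 1, true_interactor = 1, background = 18) / 20,
      interactor_effect = effects[i], bait_self_effect = 30,
      replicates = 100, cell_lines = "HCT116", biotin_hours = 6,
      treatments = "vehicle")
    sim <- generate_experiment(cfg)
    rt <- compute_ratio_table(sim)
    rt$ratio[rt$gene == "INT01"]
  }, numeric(1))
  fit <- coef(lm(observed ~ effects))
  expect_gt(fit[["effects"]], 0.9)
  expect_lt(fit[["effects"]], 1.1)
})
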