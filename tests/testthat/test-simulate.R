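test_that("configuration invariants are enforced", {
  expect_error(simulation_config(class_fractions = c(bait = 0.5, background = 0.4)),
               "sum to 1", class = "bioid_config_error")
  expect_error(simulation_config(interactor_effect = 1), class = "bioid_config_error")
  expect_error(simulation_config(bait_self_effect = 2, interactor_effect = 5),
               class = "bioid_config_error")
  expect_error(simulation_config(stress_shrinkage = 1.2), class = "bioid_config_error")
})

test_that("identical seeds give identical simulations, different seeds differ", {
  a <- generate_experiment(simulation_config(seed = 11))
  b <- generate_experiment(simulation_config(seed = 11))
  expect_identical(lapply(a$evidence, as.data.frame), lapply(b$evidence, as.data.frame))
  expect_identical(a$truth, b$truth)
  c <- generate_experiment(simulation_config(seed = 12))
  expect_false(identical(as.data.frame(a$evidence[[1]]), as.data.frame(c$evidence[[1]])))
})

test_that("ground truth covers every protein with exhaustive exclusive classes", {
  sim <- generate_experiment(simulation_config(seed = 3))
  expect_equal(nrow(sim$truth), sim$config$n_proteins)
  expect_equal(sum(sim$truth$class == "bait"), 1L)
  expect_false(anyDuplicated(sim$truth$accession) > 0)
  for (ev in sim$evidence)
    expect_setequal(ev$accession, sim$truth$accession)
})

test_that("null config yields mean ratios near 1 and planted effects are recovered", {
  # many replicates so the Monte-Carlo mean is tight
  cfg <- simulation_config(seed = 5, n_proteins = 40,
                           class_fractions = c(bait = 1, true_interactor = 1,
                                               background = 38) / 40,
                           replicates = 100, cell_lines = "HCT116",
                           biotin_hours = 6, treatments = "vehicle",
                           interactor_effect = 5, noise_log_sd = 0.2)
  sim <- generate_experiment(cfg)
  rt <- compute_ratio_table(sim)
  cls <- sim$truth$class[match(rt$accession, sim$truth$accession)]
  bgd <- rt$ratio[cls == "background"]
  expect_true(all(abs(bgd - 1) < 0.2))          # null proteins: ratio ~ 1
  int <- rt$ratio[cls == "true_interactor"]
  expect_true(int > 4 && int < 6)               # planted 5-fold effect recovered
  bait <- rt$ratio[cls == "bait"]
  expect_gt(bait, max(rt$ratio[cls != "bait"])) # self-biotinylation tops ranking
})

test_that("full shrinkage collapses stress-arm interactor ratios to 1, bait unaffected", {
  cfg <- simulation_config(seed = 6, stress_shrinkage = 1, replicates = 30,
                           cell_lines = "HCT116", biotin_hours = 6)
  sim <- generate_experiment(cfg)
  rt <- compute_ratio_table(sim)
  st <- rt[rt$treatment == "stress", ]
  cls <- sim$truth$class[match(st$accession, sim$truth$accession)]
  expect_true(all(abs(st$ratio[cls == "true_interactor"] - 1) < 0.25))
  expect_gt(st$ratio[cls == "bait"], 0.8 * cfg$bait_self_effect)
  expect_identical(sim$truth$effect_stress[sim$truth$class == "true_interactor"],
                   rep(1, sum(sim$truth$class == "true_interactor")))
})

test_that("log abundances pass a log-normality sanity check at large n", {
  n <- 6000
  cfg <- simulation_config(seed = 8, n_proteins = n,
                           class_fractions = c(bait = 1, true_interactor = 4,
                                               background = n - 5) / n,
                           replicates = 1, cell_lines = "HCT116",
                           biotin_hours = 6, treatments = "vehicle")
  sim <- generate_experiment(cfg)
  ev <- sim$evidence[[grep("ctrl", names(sim$evidence))[1]]]
  x <- log(ev$abundance[ev$abundance > 0])
  skew <- mean((x - mean(x))^3) / sd(x)^3
  expect_lt(abs(skew), 0.2)
})

test_that("planted annotations put interactors in enriched terms and span the background", {
  sim <- generate_experiment(simulation_config(seed = 9))
  ann <- plant_annotations(sim$truth, n_terms = 30, enriched_terms = 2, seed = 9)
  expect_setequal(ann$background, sort(unique(toupper(sim$truth$gene))))
  interactors <- toupper(sim$truth$gene[sim$truth$class == "true_interactor"])
  for (tid in grep("^TERM_ENR", names(ann$term_to_genes), value = TRUE))
    expect_gte(length(intersect(ann$term_to_genes[[tid]], interactors)), 8L)
  expect_error(plant_annotations(sim$truth, n_terms = 3, enriched_terms = 4),
               class = "bioid_config_error")
})

test_that("a whole-background term gets raw p-value 1 downstream", {
  sim <- generate_experiment(simulation_config(seed = 10))
  ann <- annotation_set(term = rep("ALL", nrow(sim$truth)), gene = sim$truth$gene)
  res <- run_enrichment(sim$truth$gene[1:10], ann)
  expect_equal(res$p_raw, 1)
})

test_that("simulation write-out emits readable inputs for the whole pipeline", {
  sim <- generate_experiment(simulation_config(seed = 13, n_proteins = 30,
    class_fractions = c(bait = 1, true_interactor = 3, keratin = 2,
                        endogenous_biotin = 2, background = 22) / 30,
    cell_lines = "HCT116", biotin_hours = 6))
  dir <- file.path(tempdir(), "simout")
  write_simulation(sim, dir)
  manifest <- read_run_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(manifest), length(sim$evidence))
  ev <- read_evidence(file.path(dir, paste0(manifest$run_id[1], ".tsv")),
                      manifest[1, , drop = FALSE])
  expect_equal(as.data.frame(ev), as.data.frame(sim$evidence[[manifest$run_id[1]]]))
})
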