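test_that("quartile binning is balanced and degenerate fluxes rejected", {
  cfg <- one_pair_config(n = 10001, beta_interaction = 0.3, seed = 40)
  sim <- simulate_cohort(cfg)
  qp <- quartile_variant_effects(sim$cohort, sim$genotypes[, 1],
                                 sim$fluxes[, 1])
  expect_equal(sum(qp$per_quartile$n), 10001)
  expect_lte(diff(range(qp$per_quartile$n)), 1)
  expect_true(all(qp$per_quartile$se > 0))
  expect_error(quartile_variant_effects(sim$cohort, sim$genotypes[, 1],
                                        rep(1, 10001)),
               "4 distinct values")
})

test_that("quartile trend tracks the sign of the planted interaction", {
  cfg <- one_pair_config(n = 20000, beta_interaction = 0.3, seed = 41)
  sim <- simulate_cohort(cfg)
  qp <- quartile_variant_effects(sim$cohort, sim$genotypes[, 1],
                                 sim$fluxes[, 1])
  expect_gt(qp$slope, 0)
  expect_gt(qp$slope / qp$slope_se, 2)
  # per-quartile variant effects increase from Q1 to Q4 overall
  expect_gt(qp$per_quartile$beta[4], qp$per_quartile$beta[1])

  # null interaction: slope consistent with zero, quartile effects similar
  cfg0 <- one_pair_config(n = 20000, beta_interaction = 0, seed = 42)
  sim0 <- simulate_cohort(cfg0)
  qp0 <- quartile_variant_effects(sim0$cohort, sim0$genotypes[, 1],
                                  sim0$fluxes[, 1])
  expect_lt(abs(qp0$slope), 4 * qp0$slope_se)
})

test_that("cohort comparison reports correlation and sign consistency", {
  set.seed(43)
  d <- data.frame(snp = paste0("s", 1:40), reaction = "r",
                  beta_interaction = rnorm(40, 0, 0.2),
                  slope_dosage = rnorm(40, 0, 0.2),
                  p_interaction = runif(40), p_dosage = runif(40))
  same <- compare_cohorts(d, d)
  expect_equal(same$n_shared, 40)
  expect_equal(same$r_interaction, 1)
  expect_equal(same$r_slope, 1)
  expect_equal(same$sign_consistency, 1)
  flipped <- d
  flipped$beta_interaction <- -d$beta_interaction
  expect_equal(compare_cohorts(d, flipped)$sign_consistency, 0)
  other <- d; other$snp <- paste0("x", 1:40)
  expect_error(compare_cohorts(d, other), "no shared")
})

test_that("two cohorts simulated from one truth replicate each other", {
  # 12 pairs with interaction effects spread over [-0.3, 0.3], two
  # independent cohorts per pair; strong signals should replicate
  set.seed(44)
  betas <- seq(-0.3, 0.3, length.out = 12)
  res <- lapply(c(discovery = 101, replication = 202), function(off) {
    rows <- lapply(seq_along(betas), function(i) {
      cfg <- one_pair_config(n = 8000, beta_interaction = betas[i],
                             seed = off + i)
      sim <- simulate_cohort(cfg)
      cbind(data.frame(snp = paste0("s", i), reaction = "RX1"),
            test_pair(sim$cohort, sim$genotypes[, 1], sim$fluxes[, 1]))
    })
    do.call(rbind, rows)
  })
  cmp <- compare_cohorts(res$discovery, res$replication)
  expect_equal(cmp$n_shared, 12)
  expect_gt(cmp$r_interaction, 0.7)
  expect_gt(cmp$r_slope, 0.7)
  expect_gt(cmp$sign_consistency, 0.75)
})

test_that("TSV round-trips preserve every table and the organ labels", {
  cfg <- one_pair_config(n = 200, seed = 45, cardiometabolic = TRUE)
  sim <- simulate_cohort(cfg)
  td <- withr::local_tempdir()
  pc <- file.path(td, "cohort.tsv")
  pg <- file.path(td, "geno.tsv")
  pf <- file.path(td, "flux.tsv")
  write_cohort_table(sim$cohort, pc)
  write_genotype_dosages(sim$genotypes, pg)
  write_flux_matrix(sim$fluxes, pf)
  co <- read_cohort_table(pc)
  expect_equal(co$age, sim$cohort$age, tolerance = 1e-12)
  expect_equal(co$event, sim$cohort$event)
  strip <- function(m) { m <- as.matrix(m); attributes(m) <- list(dim = dim(m)); m }
  g <- read_genotype_dosages(pg)
  expect_equal(strip(g), strip(sim$genotypes), tolerance = 1e-12)
  f <- read_flux_matrix(pf)
  expect_equal(flux_organs(f), flux_organs(sim$fluxes))
  expect_equal(strip(f), strip(sim$fluxes), tolerance = 1e-10)
  # truth file is written and readable
  pt <- file.path(td, "truth.tsv")
  write_sim_truth(sim$truth, pt)
  expect_true(any(grepl("^effect\t", readLines(pt))))
})

test_that("corrupted input tables fail schema validation by name", {
  td <- withr::local_tempdir()
  bad <- file.path(td, "cohort.tsv")
  utils::write.table(data.frame(event = c(1, 0), age = c(60, 70)),
                     bad, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_cohort_table(bad), "cohort.tsv.*sex|sex.*cohort.tsv")
  bad2 <- file.path(td, "cohort2.tsv")
  utils::write.table(data.frame(event = c(1, 2), age = c(60, 70),
                                sex = "F", array = "A"),
                     bad2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_cohort_table(bad2), "event")
})

test_that("the demo pipeline detects the planted pair end to end", {
  run <- run_pipeline(demo_config(seed = 7), snp_threshold = 1)
  sig <- run$pair_results[!is.na(run$pair_results$call) &
                            run$pair_results$call == "significant", ]
  expect_true(any(sig$snp == "rs1" & sig$reaction == "HEART_R1"))
  planted <- sig[sig$snp == "rs1" & sig$reaction == "HEART_R1", ]
  expect_equal(planted$direction, "amplification")
  # the redundant heart reaction was pruned
  expect_true("HEART_R4" %in% run$pruning_log$removed)
  # LD block structure: rs5/rs6 collapse, other SNPs are singletons
  asg <- run$blocks$assignment
  expect_equal(asg$block[asg$snp == "rs5"], asg$block[asg$snp == "rs6"])
  expect_equal(length(unique(asg$block)), 5)
  # locus aggregation covers the planted pair
  expect_true(any(run$locus_pairs$reaction == "HEART_R1"))
  # quartile profile computed for the top call
  expect_true("rs1:HEART_R1" %in% names(run$quartiles))
  expect_gt(run$quartiles[["rs1:HEART_R1"]]$slope, 0)
})

test_that("pipeline runs are deterministic and persist byte-stable tables", {
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  cfg <- demo_config(seed = 9, n_individuals = 1500)
  r1 <- run_pipeline(cfg, snp_threshold = 1, out_dir = td1)
  r2 <- run_pipeline(cfg, snp_threshold = 1, out_dir = td2)
  expect_equal(r1$pair_results, r2$pair_results)
  for (f in c("snp_screen.tsv", "pair_results.tsv", "pruning_log.tsv",
              "flux_screen.tsv", "ld_blocks.tsv", "locus_flux_pairs.tsv")) {
    expect_identical(readLines(file.path(td1, f)),
                     readLines(file.path(td2, f)))
  }
  # manifest differs only by the timestamp field
  m1 <- readLines(file.path(td1, "manifest.txt"))
  m2 <- readLines(file.path(td2, "manifest.txt"))
  diff <- m1 != m2
  expect_true(all(grepl("^timestamp", m1[diff])))
})

test_that("a configuration without reactions yields a clean empty run", {
  cfg <- sim_config(
    n_individuals = 800,
    snps = data.frame(name = c("rs1", "rs2"), maf = c(0.3, 0.4)),
    reactions = data.frame(name = character(0), organ = character(0)),
    n_pcs = 2, seed = 10)
  run <- run_pipeline(cfg, snp_threshold = 1)
  expect_equal(nrow(run$pair_results), 0)
  expect_equal(nrow(run$locus_pairs), 0)
  expect_equal(run$manifest$n_pairs_tested, 0)
})

test_that("the pipeline accepts on-disk inputs", {
  cfg <- demo_config(seed = 12, n_individuals = 1500)
  sim <- simulate_cohort(cfg)
  td <- withr::local_tempdir()
  paths <- list(cohort = file.path(td, "cohort.tsv"),
                genotypes = file.path(td, "geno.tsv"),
                fluxes = file.path(td, "flux.tsv"))
  write_cohort_table(sim$cohort, paths$cohort)
  write_genotype_dosages(sim$genotypes, paths$genotypes)
  write_flux_matrix(sim$fluxes, paths$fluxes)
  run_file <- run_pipeline(paths, snp_threshold = 1)
  run_mem <- run_pipeline(cfg, snp_threshold = 1)
  expect_equal(run_file$pair_results$beta_interaction,
               run_mem$pair_results$beta_interaction, tolerance = 1e-6)
})
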