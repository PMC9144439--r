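# small shared cohort for the experiment-design tests
make_test_cohort <- function(seed = 30, h2 = 0.8, n_markers = 300) {
  co <- simulate_cohort(sim_config(40, 44, 20, 24, n_markers = n_markers,
                                   n_chromosomes = 3, fst = 0.3,
                                   founder_fraction = 0.4, seed = seed))
  ph <- simulate_phenotypes(co$genotypes, h2 = h2, n_qtl = 40, seed = seed)
  list(G = co$genotypes, md = co$metadata, y = ph$phenotype)
}

test_that("split plans halve each pool's breeding lines into disjoint sets", {
  md <- simulate_cohort(sim_config(n_markers = 10, seed = 1))$metadata
  plan <- make_split_plan(md, seed = 2)
  expect_length(plan$a1, 30)
  expect_length(plan$a2, 30)
  expect_length(plan$m1, 42)
  expect_length(plan$m2, 42)
  expect_length(intersect(plan$a1, plan$a2), 0)
  expect_length(intersect(plan$m1, plan$m2), 0)
  expect_length(union(plan$a1, plan$m1), 72)
  expect_length(plan$random_train, 72)
  expect_setequal(c(plan$random_train, plan$random_test),
                  md$accession_id[md$class == "breeding"])
  expect_identical(make_split_plan(md, seed = 2)$a1, plan$a1)
})

test_that("odd pools split into floor/ceiling halves and errors are raised", {
  md <- data.frame(
    accession_id = sprintf("x%02d", 1:9),
    pool = c(rep("Andean", 5), rep("Mesoamerican", 4)),
    class = c(rep("breeding", 5), rep("breeding", 4)),
    stringsAsFactors = FALSE)
  plan <- make_split_plan(md, seed = 3)
  expect_length(plan$a1, 2)
  expect_length(plan$a2, 3)
  expect_setequal(c(plan$a1, plan$a2), md$accession_id[md$pool == "Andean"])
  md_none <- data.frame(accession_id = "z", pool = "Andean",
                        class = "landrace", stringsAsFactors = FALSE)
  expect_error(make_split_plan(md_none), "no breeding lines")
  plan_r <- make_split_plan(md, mode = "random", seed = 3)
  expect_null(plan_r$a1)
  expect_length(plan_r$random_train, 4)
})

test_that("the default CV design spans 7 population sizes by 11 marker counts", {
  d <- cv_design()
  expect_length(d$fractions, 7)
  expect_length(d$snp_counts, 11)
  expect_equal(d$folds, 10L)
  expect_equal(d$reps, 100L)
  expect_error(cv_design(folds = 1), "folds")
  expect_error(cv_design(fractions = c(0, 0.5)), "fractions")
})

test_that("at fraction 1 every accession is tested exactly once per replicate", {
  tc <- make_test_cohort()
  lan <- tc$md$accession_id[tc$md$class == "landrace"]
  d <- cv_design(folds = 5, reps = 1, fractions = 1, snp_counts = NA,
                 seed = 4)
  grid <- run_cv_grid(tc$G, tc$y, lan, d)
  expect_equal(nrow(grid), 1)
  expect_equal(grid$n_accessions, length(lan))
  expect_equal(grid$snp_count, ncol(tc$G$values))
  per_rep <- attr(grid, "per_rep")
  expect_equal(nrow(per_rep), 1)
  expect_equal(grid$mean_r, mean(per_rep$r))
  # reproducible given the same design seed
  grid2 <- run_cv_grid(tc$G, tc$y, lan, d)
  expect_identical(grid$mean_r, grid2$mean_r)
})

test_that("the CV grid enumerates all design cells", {
  tc <- make_test_cohort()
  lan <- tc$md$accession_id[tc$md$class == "landrace"]
  d <- cv_design(folds = 4, reps = 2, fractions = c(0.5, 1),
                 snp_counts = c(50, NA), seed = 5)
  grid <- run_cv_grid(tc$G, tc$y, lan, d)
  expect_equal(nrow(grid), 4)
  expect_setequal(grid$snp_count, c(50, ncol(tc$G$values)))
  expect_true(all(grid$n_reps == 2))
  expect_true(all(abs(grid$mean_r) <= 1))
})

test_that("find_optimum applies the plateau rule deterministically", {
  flat <- expand.grid(fraction = c(0.1, 0.5, 1), snp_count = c(100, 500))
  flat$mean_r <- 0.7
  expect_equal(find_optimum(flat)[c("fraction", "snp_count")],
               list(fraction = 0.1, snp_count = 100))

  inc <- expand.grid(fraction = c(0.1, 0.5, 1), snp_count = c(100, 500))
  inc$mean_r <- inc$fraction + inc$snp_count / 1000
  expect_equal(find_optimum(inc, tolerance = 0)[c("fraction", "snp_count")],
               list(fraction = 1, snp_count = 500))

  # plateau starting at (0.4, 2000): all later cells within tolerance
  plat <- expand.grid(fraction = c(0.1, 0.4, 1),
                      snp_count = c(500, 2000, 5000))
  plat$mean_r <- ifelse(plat$fraction >= 0.4 & plat$snp_count >= 2000,
                        0.80, 0.60)
  opt <- find_optimum(plat, tolerance = 0.01)
  expect_equal(opt$fraction, 0.4)
  expect_equal(opt$snp_count, 2000)
  expect_error(find_optimum(flat[0, ]), "empty grid")
})

test_that("pool prediction evaluates the five designs per trait", {
  tc <- make_test_cohort()
  res <- run_pool_prediction(tc$G, tc$y, tc$md, top_k = 5)
  expect_equal(nrow(res), 5)
  expect_equal(length(unique(res$design)), 5)
  expect_true(all(res$r >= -1 & res$r <= 1))
  expect_true(all(res$top_k_ratio >= 0 & res$top_k_ratio <= 1))
  # the combined-landrace designs always train on all landraces
  n_lan <- sum(tc$md$class == "landrace")
  expect_equal(res$n_train[1:3], rep(n_lan, 3))
  expect_equal(res$n_test[res$design == "landraces(An) -> breeding(An)"],
               sum(tc$md$class == "breeding" & tc$md$pool == "Andean"))
})

test_that("a heritable trait clears the null band where a null trait stays inside", {
  tc <- make_test_cohort(seed = 77, h2 = 0.9, n_markers = 400)
  res <- run_pool_prediction(tc$G, tc$y, tc$md, top_k = 5)
  comb <- res[res$design == "landraces(An+M) -> breeding(An+M)", ]
  expect_gt(comb$r, 3 / sqrt(comb$n_test))

  ph0 <- simulate_phenotypes(tc$G, h2 = 0, n_qtl = 40, seed = 78)
  res0 <- run_pool_prediction(tc$G, ph0$phenotype, tc$md, top_k = 5)
  expect_true(all(abs(res0$r) <= 3 / sqrt(res0$n_test)))
})

test_that("scenario groups assemble the designed training compositions", {
  tc <- make_test_cohort()
  plan <- make_split_plan(tc$md, seed = 6)
  res <- run_scenarios(tc$G, tc$y, tc$md, plan)
  expect_equal(res$group, paste0("G", 1:8))
  n_lan <- sum(tc$md$class == "landrace")
  expect_true(all(res$n_train == n_lan))
  expect_equal(res$n_additional,
               c(0, length(plan$a1), length(plan$a1) + length(plan$m1),
                 0, length(plan$m1), length(plan$a1) + length(plan$m1),
                 length(plan$a1) + length(plan$m1),
                 length(plan$random_train)))
  expect_equal(res$n_test[res$group == "G7"],
               length(plan$a2) + length(plan$m2))
  # G1/G4 train on landraces only
  expect_equal(res$n_additional[res$group %in% c("G1", "G4")], c(0, 0))
  # a corrupted plan with train/test overlap must abort
  bad <- plan
  bad$a1 <- c(bad$a1, bad$a2[1])
  expect_error(run_scenarios(tc$G, tc$y, tc$md, bad), "overlap")
  expect_error(run_scenarios(tc$G, tc$y, tc$md,
                             make_split_plan(tc$md, mode = "random", seed = 1)),
               "by_pool")
})
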