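#' Cross-validation design over population size and marker number
#'
#' Declares the grid of training-population fractions and marker counts
#' explored by [run_cv_grid()]. The defaults are the seven population sizes
#' (10, 20, 40, 50, 60, 80, 100%) and eleven marker numbers (100 ... 7000
#' plus all available markers, the `NA` sentinel) evaluated by ten-fold
#' cross-validation; `reps` defaults to 100 replications per cell.
#'
#' @param folds number of cross-validation folds (>= 2).
#' @param reps number of replications per grid cell.
#' @param fractions population-size fractions in `(0, 1]`.
#' @param snp_counts marker numbers; `NA` means "all available markers" and
#'   is resolved at run time.
#' @param seed integer base seed; every cell/replicate derives its own
#'   stream from it.
#' @return A list of class `cv_design`.
#' @export
cv_design <- function(folds = 10, reps = 100,
                      fractions = c(0.1, 0.2, 0.4, 0.5, 0.6, 0.8, 1),
                      snp_counts = c(100, 500, 1000, 1500, 2000, 3000,
                                     4000, 5000, 6000, 7000, NA),
                      seed = 1) {
  if (folds < 2) stop("folds must be >= 2")
  if (reps < 1) stop("reps must be >= 1")
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  structure(list(folds = as.integer(folds), reps = as.integer(reps),
                 fractions = fractions, snp_counts = snp_counts,
                 seed = as.integer(seed)),
            class = "cv_design")
}

# Coerce phenotypes (named vector, matrix or data.frame) to an
# accessions x traits matrix covering `ids`.
as_trait_matrix <- function(y, ids) {
  if (is.numeric(y) && is.null(dim(y))) {
    if (is.null(names(y))) stop("phenotype vector must be named by accession id")
    y <- matrix(y, ncol = 1, dimnames = list(names(y), "trait1"))
  } else {
    y <- as.matrix(y)
    if (is.null(rownames(y))) stop("phenotype rows must be named by accession id")
  }
  missing_ids <- setdiff(ids, rownames(y))
  if (length(missing_ids)) {
    stop("phenotypes missing for ", length(missing_ids), " accession(s)")
  }
  storage.mode(y) <- "double"
  y[ids, , drop = FALSE]
}

# Fit on train_ids and predict test_ids for one or more traits; encoding is
# always on the training scale. Returns a test x traits GEBV matrix.
fit_and_predict <- function(G, Y, train_ids, test_ids) {
  if (length(intersect(train_ids, test_ids))) {
    stop("training and testing sets overlap")
  }
  Y <- as.matrix(Y)
  enc <- genotype_encoder(G, train_ids)
  Ztr <- encode_genotypes(enc, G, train_ids)
  Zte <- encode_genotypes(enc, G, test_ids)
  rrblup_engine(Y[train_ids, , drop = FALSE], Ztr, Zte)$gebv
}

# deterministic per-(trait, cell, rep) seed below 2^31
derive_seed <- function(base, ...) {
  parts <- c(...)
  s <- as.double(base)
  for (p in parts) s <- (s * 69069 + as.double(p)) %% 2147483562
  as.integer(s) + 1L
}

#' Cross-validation grid over population size and marker number
#'
#' For every combination of population fraction and marker count in the
#' design, and for every replicate: subsample the landrace set to the
#' fraction, draw the markers proportionally per chromosome
#' ([subsample_markers()]), partition the subsample into folds, fit the
#' RR-BLUP model on the remaining folds, predict the held-out fold, and
#' compute one Pearson r on the replicate's pooled held-out predictions.
#' The grid cell reports the mean r over replicates — the predictive
#' ability of that (population size, marker number) configuration.
#'
#' @param G a filtered [genotype_matrix()].
#' @param phenotypes named numeric vector, or matrix/data.frame with
#'   accession ids as rownames (one column per trait).
#' @param landrace_ids accession ids forming the cross-validated population.
#' @param design a [cv_design()].
#' @param pool_folds if `TRUE` (default) one r per replicate is computed on
#'   the pooled held-out predictions of all folds; if `FALSE` r is computed
#'   per fold and averaged.
#' @return A data.frame of class `cv_grid` with columns `trait`,
#'   `fraction`, `snp_count`, `n_accessions`, `mean_r`, `n_reps`; the
#'   per-replicate correlations are in `attr(, "per_rep")`.
#' @export
run_cv_grid <- function(G, phenotypes, landrace_ids, design = cv_design(),
                        pool_folds = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(design, "cv_design"))
  Y <- as_trait_matrix(phenotypes, landrace_ids)
  n <- length(landrace_ids)
  if (n < design$folds) stop("landrace set smaller than the number of folds")
  m_avail <- ncol(G$values)
  snp_counts <- ifelse(is.na(design$snp_counts), m_avail, design$snp_counts)
  if (any(snp_counts > m_avail)) {
    stop("snp_counts exceed the available markers")
  }
  cells <- expand.grid(fraction = design$fractions, snp_count = snp_counts,
                       KEEP.OUT.ATTRS = FALSE)
  grid_rows <- list()
  rep_rows <- list()
  for (t in seq_len(ncol(Y))) {
    trait <- colnames(Y)[t]
    for (ci in seq_len(nrow(cells))) {
      frac <- cells$fraction[ci]
      n_snp <- cells$snp_count[ci]
      n_sub <- max(design$folds, round(frac * n))
      rs <- numeric(design$reps)
      for (rep in seq_len(design$reps)) {
        s <- derive_seed(design$seed, t, ci, rep)
        Gs <- subsample_markers(G, n_snp, seed = s)
        set.seed(s)
        sub_ids <- if (n_sub < n) sample(landrace_ids, n_sub) else landrace_ids
        fold_id <- sample(rep(seq_len(design$folds), length.out = n_sub))
        if (min(table(fold_id)) < 2L) {
          stop("a fold has fewer than 2 testing accessions")
        }
        preds <- numeric(n_sub)
        fold_r <- numeric(design$folds)
        for (f in seq_len(design$folds)) {
          te <- sub_ids[fold_id == f]
          tr <- sub_ids[fold_id != f]
          gebv <- drop(fit_and_predict(Gs, Y[, t, drop = FALSE], tr, te))
          preds[fold_id == f] <- gebv
          if (!pool_folds) {
            fold_r[f] <- predictive_ability(gebv, Y[te, t])
          }
        }
        rs[rep] <- if (pool_folds) {
          predictive_ability(preds, Y[sub_ids, t])
        } else {
          mean(fold_r)
        }
      }
      grid_rows[[length(grid_rows) + 1L]] <- data.frame(
        trait = trait, fraction = frac, snp_count = n_snp,
        n_accessions = n_sub, mean_r = mean(rs), n_reps = design$reps,
        stringsAsFactors = FALSE)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        trait = trait, fraction = frac, snp_count = n_snp,
        replicate = seq_len(design$reps), r = rs, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, grid_rows)
  attr(out, "per_rep") <- do.call(rbind, rep_rows)
  class(out) <- c("cv_grid", class(out))
  out
}

#' Find the optimal population size and marker number
#'
#' Selects the most economical grid cell whose predictive ability is within
#' `tolerance` of the grid maximum: among all cells with
#' `mean_r >= max(mean_r) - tolerance`, the one with the smallest
#' population fraction, then the smallest marker count. This is a plateau
#' rule — predictive ability stops improving appreciably beyond a certain
#' population size and marker density, so the cheapest near-optimal
#' configuration is reported.
#'
#' @param grid a [run_cv_grid()] result (or any data.frame with columns
#'   `fraction`, `snp_count`, `mean_r`, optionally `trait`).
#' @param trait trait name to select when the grid holds several.
#' @param tolerance absolute tolerance on r (default 0.01).
#' @return A list with `fraction` (`opt_pop`), `snp_count` (`opt_snp`) and
#'   `mean_r` of the selected cell.
#' @export
find_optimum <- function(grid, trait = NULL, tolerance = 0.01) {
  g <- as.data.frame(grid)
  if (!is.null(trait)) {
    if (!"trait" %in% names(g)) stop("grid has no trait column")
    g <- g[g$trait == trait, , drop = FALSE]
  } else if ("trait" %in% names(g) && length(unique(g$trait)) > 1L) {
    stop("grid holds several traits; supply `trait`")
  }
  if (nrow(g) == 0L) stop("empty grid")
  cand <- g[g$mean_r >= max(g$mean_r) - tolerance, , drop = FALSE]
  cand <- cand[order(cand$fraction, cand$snp_count), , drop = FALSE]
  list(fraction = cand$fraction[1L], snp_count = cand$snp_count[1L],
       mean_r = cand$mean_r[1L])
}

#' Half-split plan of breeding lines for training-set optimization
#'
#' Splits the breeding lines into random halves, the raw material of the
#' training-set optimization scenarios: in `by_pool` mode each gene pool's
#' breeding lines are split separately (Andean halves A1/A2, Mesoamerican
#' halves M1/M2, with |A1| = floor(n/2)), and a pooled random half-split
#' (ignoring gene pool) is drawn from the same seed stream for the paired
#' random-selection comparison; in `random` mode only the pooled split is
#' drawn. With the default cohort composition (60 Andean and 84
#' Mesoamerican breeding lines) the plan gives |A1| = |A2| = 30,
#' |M1| = |M2| = 42 and |A1 u M1| = 72.
#'
#' @param metadata cohort metadata (columns `accession_id`, `pool`,
#'   `class`).
#' @param mode `"by_pool"` or `"random"`.
#' @param seed integer RNG seed.
#' @return An object of class `split_plan` with id vectors `a1`, `a2`,
#'   `m1`, `m2` (in `by_pool` mode), `random_train`, `random_test`, plus
#'   `mode` and `seed`.
#' @export
make_split_plan <- function(metadata, mode = c("by_pool", "random"),
                            seed = 1) {
  mode <- match.arg(mode)
  b <- metadata[metadata$class == "breeding", , drop = FALSE]
  if (nrow(b) == 0L) stop("no breeding lines in the metadata")
  set.seed(seed)
  plan <- list(mode = mode, seed = as.integer(seed),
               a1 = NULL, a2 = NULL, m1 = NULL, m2 = NULL)
  if (mode == "by_pool") {
    an <- b$accession_id[b$pool == "Andean"]
    me <- b$accession_id[b$pool == "Mesoamerican"]
    if (length(an) < 2L || length(me) < 2L) {
      stop("by_pool mode needs at least 2 breeding lines per pool")
    }
    plan$a1 <- sort(sample(an, floor(length(an) / 2)))
    plan$a2 <- sort(setdiff(an, plan$a1))
    plan$m1 <- sort(sample(me, floor(length(me) / 2)))
    plan$m2 <- sort(setdiff(me, plan$m1))
  }
  all_b <- b$accession_id
  plan$random_train <- sort(sample(all_b, floor(length(all_b) / 2)))
  plan$random_test <- sort(setdiff(all_b, plan$random_train))
  structure(plan, class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("split_plan (", x$mode, " mode, seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$a1)) {
    cat(sprintf("  Andean halves:       A1 = %d, A2 = %d\n",
                length(x$a1), length(x$a2)))
    cat(sprintf("  Mesoamerican halves: M1 = %d, M2 = %d\n",
                length(x$m1), length(x$m2)))
  }
  cat(sprintf("  pooled random halves: %d / %d\n",
              length(x$random_train), length(x$random_test)))
  invisible(x)
}

#' Gene-pool combine/assign prediction designs
#'
#' Evaluates the five landrace-to-breeding-line prediction designs: the
#' combined landraces (An + M) predicting all breeding lines, the Andean
#' breeding lines, and the Mesoamerican breeding lines; and each pool's
#' landraces predicting its own breeding lines (An -> An, M -> M). Each
#' design is a single deterministic fit followed by [predictive_ability()]
#' on the testing set, plus the top-k and top-fraction overlap ratios.
#'
#' @param G a filtered [genotype_matrix()].
#' @param phenotypes named vector or accession-id-rowed matrix/data.frame.
#' @param metadata cohort metadata (`accession_id`, `pool`, `class`).
#' @param top_k top-set size for [topk_overlap()] (capped at the testing-set
#'   size); default 30.
#' @param top_fraction top fraction for [topk_overlap()]; default 0.3.
#' @return A data.frame with one row per trait x design: columns `trait`,
#'   `design`, `n_train`, `n_test`, `r`, `top_k_ratio`, `top_frac_ratio`.
#' @export
run_pool_prediction <- function(G, phenotypes, metadata,
                                top_k = 30, top_fraction = 0.3) {
  stopifnot(inherits(G, "genotype_matrix"))
  ids <- accessions(G)
  lan <- metadata$accession_id[metadata$class == "landrace"]
  bre <- metadata$accession_id[metadata$class == "breeding"]
  lan_an <- metadata$accession_id[metadata$class == "landrace" &
                                    metadata$pool == "Andean"]
  lan_m <- metadata$accession_id[metadata$class == "landrace" &
                                   metadata$pool == "Mesoamerican"]
  bre_an <- metadata$accession_id[metadata$class == "breeding" &
                                    metadata$pool == "Andean"]
  bre_m <- metadata$accession_id[metadata$class == "breeding" &
                                   metadata$pool == "Mesoamerican"]
  designs <- list(
    "landraces(An+M) -> breeding(An+M)" = list(train = lan, test = bre),
    "landraces(An+M) -> breeding(An)" = list(train = lan, test = bre_an),
    "landraces(An+M) -> breeding(M)" = list(train = lan, test = bre_m),
    "landraces(An) -> breeding(An)" = list(train = lan_an, test = bre_an),
    "landraces(M) -> breeding(M)" = list(train = lan_m, test = bre_m)
  )
  Y <- as_trait_matrix(phenotypes, ids)
  rows <- list()
  for (d in names(designs)) {
    tr <- designs[[d]]$train
    te <- designs[[d]]$test
    if (length(te) == 0L) stop("empty testing set in design ", d)
    gebv <- fit_and_predict(G, Y, tr, te)
    k <- min(top_k, length(te))
    for (t in seq_len(ncol(Y))) {
      obs <- Y[te, t]
      rows[[length(rows) + 1L]] <- data.frame(
        trait = colnames(Y)[t], design = d,
        n_train = length(tr), n_test = length(te),
        r = predictive_ability(gebv[, t], obs),
        top_k_ratio = topk_overlap(gebv[, t], obs, k = k),
        top_frac_ratio = topk_overlap(gebv[, t], obs, fraction = top_fraction),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$trait, colnames(Y)),
                   match(out$design, names(designs))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Training-set optimization scenarios G1-G8
#'
#' Runs the eight training-set compositions of the two-step optimization
#' design. Scenario 1 asks whether adding half of a gene pool's breeding
#' lines to the landrace training set improves prediction of the remaining
#' half: G1 (landraces only -> A2), G2 (+A1 -> A2), G3 (+A1+M1 -> A2), G4
#' (landraces only -> M2), G5 (+M1 -> M2), G6 (+A1+M1 -> M2). Scenario 2
#' compares selecting the added half by gene pool against selecting it at
#' random: G7 (+A1+M1 -> A2+M2) versus G8 (+random half -> remaining half).
#' Every group is one deterministic fit plus [predictive_ability()];
#' training (including additional) and testing sets are asserted disjoint.
#'
#' @param G a filtered [genotype_matrix()].
#' @param phenotypes named vector or accession-id-rowed matrix/data.frame.
#' @param metadata cohort metadata (`accession_id`, `pool`, `class`).
#' @param plan a `by_pool` [make_split_plan()].
#' @return A data.frame with one row per trait x group: columns `trait`,
#'   `group`, `n_train`, `n_additional`, `n_test`, `r`.
#' @export
run_scenarios <- function(G, phenotypes, metadata, plan) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(plan, "split_plan"))
  if (is.null(plan$a1)) stop("run_scenarios requires a by_pool split plan")
  lan <- metadata$accession_id[metadata$class == "landrace"]
  groups <- list(
    G1 = list(add = character(0), test = plan$a2),
    G2 = list(add = plan$a1, test = plan$a2),
    G3 = list(add = c(plan$a1, plan$m1), test = plan$a2),
    G4 = list(add = character(0), test = plan$m2),
    G5 = list(add = plan$m1, test = plan$m2),
    G6 = list(add = c(plan$a1, plan$m1), test = plan$m2),
    G7 = list(add = c(plan$a1, plan$m1), test = c(plan$a2, plan$m2)),
    G8 = list(add = plan$random_train, test = plan$random_test)
  )
  ids <- accessions(G)
  Y <- as_trait_matrix(phenotypes, ids)
  rows <- list()
  for (g in names(groups)) {
    add <- groups[[g]]$add
    te <- groups[[g]]$test
    tr <- c(lan, add)
    if (length(intersect(tr, te))) {
      stop("training and testing sets overlap in group ", g)
    }
    gebv <- fit_and_predict(G, Y, tr, te)
    for (t in seq_len(ncol(Y))) {
      rows[[length(rows) + 1L]] <- data.frame(
        trait = colnames(Y)[t], group = g,
        n_train = length(lan), n_additional = length(add),
        n_test = length(te),
        r = predictive_ability(gebv[, t], Y[te, t]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$trait, colnames(Y)),
                   match(out$group, names(groups))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
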