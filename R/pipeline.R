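# End-to-end hybrid-zone analysis: covariate handling, group construction,
# allometry correction, group-level statistics, and report assembly.

#' Assign specimens to decile admixture groups
#'
#' Bins specimens by percentage of admixed alleles: group `g` covers
#' `[10g, 10(g+1))`, with group 9 closed at 100. Produces a per-group summary
#' (count, family count, sex counts, mean percentage) and the step statistics
#' between consecutive observed group means.
#'
#' @param covariates Data frame with columns `specimen_id` and `pct_dom`
#'   (0-100); `family_id` and `sex` are summarized when present.
#' @return A list of class `hybrid_grouping`: `covariates` (input plus a
#'   `group` column), `group_table`, `step_stats` (`mean`, `min`, `max` of
#'   differences between successive observed group mean percentages).
#' @export
assign_hybrid_groups <- function(covariates) {
  stopifnot(is.data.frame(covariates),
            all(c("specimen_id", "pct_dom") %in% names(covariates)))
  p <- covariates$pct_dom
  if (any(!is.finite(p)) || any(p < 0 | p > 100)) {
    stop("pct_dom must lie in [0, 100]", call. = FALSE)
  }
  covariates$group <- pmin(floor(p / 10), 9L)
  observed <- sort(unique(covariates$group))
  tab <- do.call(rbind, lapply(observed, function(g) {
    sub <- covariates[covariates$group == g, ]
    data.frame(
      group = g,
      pct_range = sprintf("%d-%d", 10 * g, if (g == 9L) 100L else 10L * g + 9L),
      n = nrow(sub),
      n_families = if ("family_id" %in% names(sub)) length(unique(sub$family_id)) else NA_integer_,
      n_male = if ("sex" %in% names(sub)) sum(tolower(substr(sub$sex, 1, 1)) == "m") else NA_integer_,
      n_female = if ("sex" %in% names(sub)) sum(tolower(substr(sub$sex, 1, 1)) == "f") else NA_integer_,
      mean_pct_dom = mean(sub$pct_dom)
    )
  }))
  steps <- diff(tab$mean_pct_dom)
  structure(
    list(covariates = covariates, group_table = tab,
         step_stats = list(mean = mean(steps), min = min(steps), max = max(steps))),
    class = "hybrid_grouping"
  )
}

#' Remove allometric shape variation
#'
#' Replaces the symmetric shape coordinates by the residuals of a
#' multivariate regression of shape on centroid size (grand mean added back)
#' and reports the percentage of shape variance attributable to size.
#'
#' @param sample An `aligned_sample` from [decompose_symmetry()].
#' @return A list of class `allometry_correction`: `sample` (corrected),
#'   `pct_var_explained`, `coefficient_vector` (shape change per unit
#'   centroid size).
#' @export
remove_allometry <- function(sample) {
  stopifnot(inherits(sample, "aligned_sample"))
  cs <- sample$centroid_sizes
  if (stats::var(cs) <= 0) stop("centroid size is constant; allometry is undefined", call. = FALSE)
  X <- sample$symmetric
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  csc <- cs - mean(cs)
  b <- drop(crossprod(Xc, csc)) / sum(csc^2)
  pred <- outer(csc, b)
  resid <- Xc - pred
  pct <- 100 * sum(pred^2) / sum(Xc^2)
  sample$symmetric <- sweep(resid, 2L, mu, `+`)
  sample$allometry_removed <- TRUE
  structure(list(sample = sample, pct_var_explained = pct, coefficient_vector = b),
            class = "allometry_correction")
}

#' Pool the extreme admixture groups
#'
#' Pools groups 0-1 into a `mus` side and groups 8-9 into a `dom` side, the
#' robust proxies for the two parental taxa.
#'
#' @param grouping A [assign_hybrid_groups()] result, or a data frame with
#'   `group` and `pct_dom` columns.
#' @return A list: `labels` (factor `mus`/`dom`, `NA` for intermediate
#'   groups, in specimen order) and `summary` (per-side n, mean/min/max
#'   percentage).
#' @export
pool_extremes <- function(grouping) {
  cov <- if (inherits(grouping, "hybrid_grouping")) grouping$covariates else grouping
  stopifnot(all(c("group", "pct_dom") %in% names(cov)))
  side <- rep(NA_character_, nrow(cov))
  side[cov$group %in% c(0L, 1L)] <- "mus"
  side[cov$group %in% c(8L, 9L)] <- "dom"
  if (!any(side == "mus", na.rm = TRUE)) stop("no specimens in groups 0-1 to pool", call. = FALSE)
  if (!any(side == "dom", na.rm = TRUE)) stop("no specimens in groups 8-9 to pool", call. = FALSE)
  labels <- factor(side, levels = c("mus", "dom"))
  summ <- do.call(rbind, lapply(levels(labels), function(s) {
    p <- cov$pct_dom[which(labels == s)]
    data.frame(side = s, n = length(p), mean_pct_dom = mean(p),
               min_pct_dom = min(p), max_pct_dom = max(p))
  }))
  list(labels = labels, summary = summ)
}

# PCA-reduce a pooled pair of groups and run Hotelling + LOOCV DA, backing
# off to fewer components while the pooled covariance is singular.
compare_pair <- function(X, labels, n_pcs) {
  labels <- droplevels(factor(labels))
  n <- nrow(X)
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  usable <- sum(fit$sdev > 1e-9 * fit$sdev[1])
  # n - 3 keeps the leave-one-out training folds' within-class covariance
  # nonsingular (n - 1 samples, 2 classes)
  p_try <- max(min(n_pcs, n - 3L, usable), 1L)
  while (p_try >= 1L) {
    scores <- fit$x[, seq_len(p_try), drop = FALSE]
    ht <- tryCatch(hotelling_two_sample(scores[labels == levels(labels)[1], , drop = FALSE],
                                        scores[labels == levels(labels)[2], , drop = FALSE]),
                   error = function(e) NULL)
    if (!is.null(ht)) {
      mis <- tryCatch(lda_loocv(scores, labels), error = function(e) NA_real_)
      pct_pcs <- 100 * sum(fit$sdev[seq_len(p_try)]^2) / sum(fit$sdev^2)
      return(list(hotelling = ht, misclassification = mis, n_pcs_used = p_try,
                  pct_var_pcs = pct_pcs))
    }
    p_try <- p_try - 1L
  }
  stop("no usable principal components for this pair", call. = FALSE)
}

#' Run the full hybrid-zone shape analysis
#'
#' Executes the complete analysis on one trait: symmetry decomposition,
#' allometry removal, decile group assignment, centroid-size analyses,
#' comparison of the pooled extremes (PCA to `n_pcs` components, Hotelling
#' test, Procrustes distance, leave-one-out discriminant validation),
#' gradient analyses (permutation regression of shape on admixture
#' percentage, between-group PCA, per-group phenotypic variance and mean
#' fluctuating asymmetry), all pairwise group comparisons (per-pair PCA
#' re-fit on each pooled pair, Holm correction across pairs), the Mantel test
#' of Procrustes versus genomic distance (all pairs and the subset with
#' genomic distance below 20 percentage points), and the directionality
#' analysis of pairwise shape-change vectors against the mus-to-dom vector
#' (vectors oriented from lower to higher mean admixture, Holm-corrected
#' angle tests).
#'
#' @param landmarks Raw configurations: an `L x 3 x N` array (object
#'   symmetry) or `list(left = , right = )` of `k x 3 x N` arrays (matching
#'   symmetry), with specimen ids as third `dimnames`.
#' @param scheme A [symmetry_scheme()].
#' @param covariates Data frame with `specimen_id`, `pct_dom` and optionally
#'   `family_id`, `sex`, `age_weeks`.
#' @param n_pcs Components retained for the pairwise and extremes tests.
#' @param n_perm Permutations for the regression and Mantel tests.
#' @param seed Integer seed; the run is bit-identical under a fixed seed.
#' @param angle_dim Dimensionality used by the angle-test null; defaults to
#'   the symmetric shape-space dimension of `scheme`.
#' @return An object of class `analysis_report`; see the package vignette
#'   for the table layouts.
#' @export
run_full_pipeline <- function(landmarks, scheme, covariates, n_pcs = 10L,
                              n_perm = 10000L, seed = NULL, angle_dim = NULL) {
  stopifnot(inherits(scheme, "symmetry_scheme"), is.data.frame(covariates))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  warn_log <- character()

  ids <- if (scheme$mode == "object") dimnames(as_array3d(landmarks))[[3]]
         else dimnames(as_array3d(landmarks$left))[[3]]
  if (!is.null(ids)) {
    if (!setequal(ids, covariates$specimen_id)) {
      stop("covariate specimen_id set does not match the landmark specimen ids",
           call. = FALSE)
    }
    covariates <- covariates[match(ids, covariates$specimen_id), , drop = FALSE]
  } else if (nrow(covariates) != (if (scheme$mode == "object") dim(as_array3d(landmarks))[3]
                                  else dim(as_array3d(landmarks$left))[3])) {
    stop("covariate rows do not match the number of specimens", call. = FALSE)
  }

  sample <- stage("symmetry decomposition",
                  decompose_symmetry(landmarks, scheme,
                                     specimen_id = covariates$specimen_id))
  fa <- stage("fluctuating asymmetry", fa_scores(sample))

  allom <- stage("allometry removal", remove_allometry(sample))
  X <- allom$sample$symmetric
  cs <- sample$centroid_sizes

  grouping <- stage("group assignment", assign_hybrid_groups(covariates))
  group <- grouping$covariates$group
  gtab <- grouping$group_table

  covariate_checks <- stage("covariate checks", {
    out <- list()
    if ("sex" %in% names(covariates) && length(unique(covariates$sex)) == 2L) {
      sx <- shape_regression_permutation(X, as.numeric(factor(covariates$sex)),
                                         n_perm = min(n_perm, 999L),
                                         seed = derive_seed(seed, 11L))
      out$sex_pct <- sx$pct_var_explained
      out$sex_p <- sx$p_perm
    }
    if ("age_weeks" %in% names(covariates) && stats::var(covariates$age_weeks) > 0) {
      ag <- shape_regression_permutation(X, covariates$age_weeks,
                                         n_perm = min(n_perm, 999L),
                                         seed = derive_seed(seed, 12L))
      out$age_pct <- ag$pct_var_explained
      out$age_p <- ag$p_perm
    }
    out
  })

  size_results <- stage("size analyses", {
    ct <- stats::cor.test(cs, covariates$pct_dom)
    proxies <- c(mus = if (0L %in% gtab$group) mean(cs[group == 0L]) else NA_real_,
                 dom = if (9L %in% gtab$group) mean(cs[group == 9L]) else NA_real_)
    list(r = unname(ct$estimate), p = ct$p.value, proxy_means = proxies,
         group_means = tapply(cs, group, mean),
         pairwise = pairwise_rank_test(cs, group))
  })

  pooling <- stage("extremes pooling", pool_extremes(grouping))
  extremes <- stage("extremes comparison", {
    keep <- !is.na(pooling$labels)
    cmp <- compare_pair(X[keep, , drop = FALSE], pooling$labels[keep], n_pcs)
    mus_mean <- colMeans(X[keep & pooling$labels == "mus", , drop = FALSE])
    dom_mean <- colMeans(X[keep & pooling$labels == "dom", , drop = FALSE])
    list(pooling = pooling$summary, hotelling = cmp$hotelling,
         n_pcs_used = cmp$n_pcs_used, pct_var_pcs = cmp$pct_var_pcs,
         misclassification = cmp$misclassification,
         procrustes_distance = procrustes_distance(mus_mean, dom_mean),
         mus_mean = mus_mean, dom_mean = dom_mean)
  })

  gradient <- stage("gradient analyses", {
    reg <- shape_regression_permutation(X, covariates$pct_dom, n_perm = n_perm,
                                        seed = derive_seed(seed, 1L))
    bg <- between_group_pca(X, group)
    gv <- do.call(rbind, lapply(gtab$group, function(g) {
      Xg <- X[group == g, , drop = FALSE]
      v <- if (nrow(Xg) > 1L) sum(sweep(Xg, 2L, colMeans(Xg))^2) / (nrow(Xg) - 1L) else NA_real_
      data.frame(group = g, n = nrow(Xg), variance = v, rms = sqrt(v))
    }))
    gv$mean_fa <- as.numeric(tapply(fa$per_specimen, factor(group, levels = gtab$group), mean))
    list(regression = reg, bgpca = bg, group_variance = gv)
  })

  # group means for distances and directions, on corrected shapes
  means <- t(vapply(gtab$group, function(g) colMeans(X[group == g, , drop = FALSE]),
                    numeric(ncol(X))))
  rownames(means) <- as.character(gtab$group)

  testable <- gtab$group[gtab$n >= 2L]
  if (length(testable) < length(gtab$group)) {
    dropped <- setdiff(gtab$group, testable)
    warn_log <- c(warn_log, sprintf("groups with n < 2 excluded from pairwise tests: %s",
                                    paste(dropped, collapse = ", ")))
    warning(warn_log[length(warn_log)], call. = FALSE)
  }
  pairs_idx <- if (length(testable) >= 2L) utils::combn(testable, 2L) else
    matrix(integer(), 2L, 0L)

  pairwise_table <- stage("pairwise comparisons", {
    rows <- lapply(seq_len(ncol(pairs_idx)), function(j) {
      g1 <- pairs_idx[1L, j]; g2 <- pairs_idx[2L, j]
      sel <- group %in% c(g1, g2)
      cmp <- compare_pair(X[sel, , drop = FALSE], group[sel], n_pcs)
      data.frame(
        group_1 = g1, group_2 = g2,
        n_1 = sum(group == g1), n_2 = sum(group == g2),
        n_pcs_used = cmp$n_pcs_used,
        t2 = cmp$hotelling$t2, df1 = cmp$hotelling$df1, df2 = cmp$hotelling$df2,
        p_raw = cmp$hotelling$p_raw,
        misclassification_pct = 100 * cmp$misclassification,
        procrustes_distance = procrustes_distance(means[as.character(g1), ],
                                                  means[as.character(g2), ]),
        genomic_distance = abs(gtab$mean_pct_dom[gtab$group == g2] -
                               gtab$mean_pct_dom[gtab$group == g1])
      )
    })
    tab <- do.call(rbind, rows)
    if (!is.null(tab)) tab$p_holm <- holm_adjust(tab$p_raw)
    tab
  })

  distance_correlation <- stage("distance correlation", {
    gl <- as.character(gtab$group)
    Dp <- matrix(0, length(gl), length(gl), dimnames = list(gl, gl))
    Dg <- Dp
    for (a in seq_along(gl)) for (b in seq_along(gl)) {
      Dp[a, b] <- procrustes_distance(means[a, ], means[b, ])
      Dg[a, b] <- abs(gtab$mean_pct_dom[a] - gtab$mean_pct_dom[b])
    }
    mt <- mantel_test(Dp, Dg, n_perm = n_perm, seed = derive_seed(seed, 2L))
    # subset of pairs closer than 20 percentage points: correlation over that
    # fixed pair set, permutation on the shape-distance matrix
    ut <- upper.tri(Dg)
    sel <- ut & Dg < 20
    sub <- if (sum(sel) >= 3L) {
      r_sub <- stats::cor(Dp[sel], Dg[sel])
      r_perm <- with_seed(derive_seed(seed, 3L), {
        vapply(seq_len(n_perm), function(i) {
          idx <- sample.int(nrow(Dp))
          stats::cor(Dp[idx, idx][sel], Dg[sel])
        }, numeric(1))
      })
      list(r = r_sub, p_perm = (sum(abs(r_perm) >= abs(r_sub)) + 1) / (n_perm + 1),
           n_pairs = sum(sel))
    } else {
      list(r = NA_real_, p_perm = NA_real_, n_pairs = sum(sel))
    }
    list(mantel = mt, subset_lt20 = sub,
         procrustes_matrix = Dp, genomic_matrix = Dg)
  })

  direction_table <- stage("direction analysis", {
    ref <- extremes$dom_mean - extremes$mus_mean
    adim <- angle_dim %||% shape_space_dim(scheme)
    rows <- lapply(seq_len(ncol(pairs_idx)), function(j) {
      g1 <- pairs_idx[1L, j]; g2 <- pairs_idx[2L, j]
      p1 <- gtab$mean_pct_dom[gtab$group == g1]
      p2 <- gtab$mean_pct_dom[gtab$group == g2]
      lo <- if (p1 <= p2) g1 else g2
      hi <- if (p1 <= p2) g2 else g1
      v <- means[as.character(hi), ] - means[as.character(lo), ]
      at <- angle_test(v, ref, dim = adim)
      data.frame(group_low = lo, group_high = hi, angle_deg = at$angle_deg,
                 dim = at$dim, p_raw = at$p_raw)
    })
    tab <- do.call(rbind, rows)
    if (!is.null(tab)) {
      tab$p_holm <- holm_adjust(tab$p_raw)
      tab$consistent <- tab$p_holm < 0.05
    }
    tab
  })

  structure(
    list(trait = scheme$mode, scheme = scheme, n_pcs = as.integer(n_pcs),
         n_perm = as.integer(n_perm), seed = seed,
         grouping = grouping, group_table = gtab,
         size_results = size_results, allometry = allom[c("pct_var_explained",
                                                          "coefficient_vector")],
         covariate_checks = covariate_checks,
         extremes_comparison = extremes, gradient_results = gradient,
         pairwise_table = pairwise_table,
         distance_correlation = distance_correlation,
         direction_table = direction_table,
         fa = fa, sample = allom$sample, warnings = warn_log),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  g <- x$group_table
  cat(sprintf("Hybrid-zone shape analysis (%s symmetry)\n", x$trait))
  cat(sprintf("  %d specimens in %d admixture groups (%s)\n",
              sum(g$n), nrow(g), paste(g$group, collapse = ", ")))
  cat(sprintf("  allometry: %.1f%% of shape variance (removed)\n",
              x$allometry$pct_var_explained))
  reg <- x$gradient_results$regression
  cat(sprintf("  shape ~ admixture: %.1f%% of variance, p = %.4g (%d perms)\n",
              reg$pct_var_explained, reg$p_perm, reg$n_perm))
  ex <- x$extremes_comparison
  cat(sprintf("  extremes (mus vs dom): T2(%d, %d) = %.1f, p = %.3g, misclassified %.1f%%, Procrustes distance %.4f\n",
              ex$hotelling$df1, ex$hotelling$df2, ex$hotelling$t2,
              ex$hotelling$p_raw, 100 * ex$misclassification,
              ex$procrustes_distance))
  mt <- x$distance_correlation$mantel
  cat(sprintf("  Procrustes vs genomic distance: Mantel r = %.2f, p = %.4g\n",
              mt$r, mt$p_perm))
  if (!is.null(x$pairwise_table)) {
    cat(sprintf("  pairwise mean-shape tests: %d of %d pairs significant (Holm p < 0.05)\n",
                sum(x$pairwise_table$p_holm < 0.05), nrow(x$pairwise_table)))
  }
  if (!is.null(x$direction_table)) {
    cat(sprintf("  directionality: %d of %d pairwise vectors consistent with the mus-to-dom direction\n",
                sum(x$direction_table$consistent), nrow(x$direction_table)))
  }
  invisible(x)
}
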