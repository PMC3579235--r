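#' Estimate negative-binomial dispersion by conditional likelihood
#'
#' With libraries of (near-)equal size and equal means within each group,
#' the distribution of a gene's per-library counts conditional on their
#' group total is free of the mean, leaving a likelihood in the dispersion
#' `phi` alone (variance = `mu + phi mu^2`; NB size `r = 1/phi`):
#' `l_g(phi) = sum_i lgamma(y_i + r) - n lgamma(r) + lgamma(n r) - lgamma(z + n r)`
#' summed over groups. The common dispersion maximizes the sum of `l_g`
#' over genes; tagwise estimates maximize
#' `l_g(phi) + shrinkage_weight * mean_g l_g(phi)`, shrinking each gene
#' toward the common value — exactly to it as the weight grows.
#'
#' @param counts Wide count tibble (raw counts).
#' @param groups Character/factor vector of group labels, one per library
#'   column (in column order), or a named vector keyed by library id.
#' @param shrinkage_weight Weight of the common-likelihood penalty in the
#'   tagwise fit (default 10).
#' @param phi_max Upper bound of the dispersion search (default 5).
#' @return A list of class `sage_dispersion` with `common` (scalar),
#'   `tagwise` (named per-gene vector) and `shrinkage_weight`.
#' @export
estimate_dispersion <- function(counts, groups, shrinkage_weight = 10,
                                phi_max = 5) {
  m <- counts_to_matrix(counts)
  if (all(m == 0)) abort("all counts are zero")
  if (!is.null(names(groups))) groups <- groups[colnames(m)]
  if (length(groups) != ncol(m)) {
    abort("`groups` must give one group per library")
  }
  groups <- as.character(groups)
  if (max(table(groups)) < 2) abort("need >= 2 libraries in >= 1 group")
  split_idx <- split(seq_len(ncol(m)), groups)

  cl_gene <- function(phi) {
    # matrix of per-gene conditional log-likelihood at dispersion phi
    r <- 1 / phi
    out <- numeric(nrow(m))
    for (idx in split_idx) {
      yg <- m[, idx, drop = FALSE]
      ng <- length(idx)
      z <- rowSums(yg)
      out <- out + rowSums(lgamma(yg + r)) - ng * lgamma(r) +
        lgamma(ng * r) - lgamma(z + ng * r)
    }
    out
  }

  lo <- 1e-6
  common <- stats::optimize(function(lp) sum(cl_gene(exp(lp))),
                            interval = log(c(lo, phi_max)),
                            maximum = TRUE, tol = 1e-6)
  common_phi <- exp(common$maximum)
  # treat a boundary solution as (numerically) zero dispersion
  if (common$maximum <= log(lo) + 1e-3) common_phi <- 0

  # spline of the averaged common likelihood over a log-phi grid, so the
  # per-gene optimizations stay O(1) in the number of genes
  grid <- exp(seq(log(lo), log(phi_max), length.out = 60))
  cl_on_grid <- vapply(grid, cl_gene, numeric(nrow(m)))
  mean_cl <- stats::splinefun(log(grid), colMeans(cl_on_grid))

  per_gene_cl <- function(g, phi) {
    r <- 1 / phi
    out <- 0
    for (idx in split_idx) {
      yg <- m[g, idx]
      ng <- length(idx)
      out <- out + sum(lgamma(yg + r)) - ng * lgamma(r) +
        lgamma(ng * r) - lgamma(sum(yg) + ng * r)
    }
    out
  }
  tagwise <- vapply(seq_len(nrow(m)), function(g) {
    opt <- stats::optimize(
      function(lp) per_gene_cl(g, exp(lp)) + shrinkage_weight * mean_cl(lp),
      interval = log(c(lo, phi_max)), maximum = TRUE, tol = 1e-5
    )
    if (opt$maximum <= log(lo) + 1e-3) 0 else exp(opt$maximum)
  }, numeric(1))

  structure(
    list(common = common_phi,
         tagwise = setNames(tagwise, rownames(m)),
         shrinkage_weight = shrinkage_weight),
    class = "sage_dispersion"
  )
}

#' @export
print.sage_dispersion <- function(x, ...) {
  cat("NB dispersion: common =", signif(x$common, 4),
      "| tagwise range:", paste(signif(range(x$tagwise), 3), collapse = "-"),
      "\n")
  invisible(x)
}

# Two-sided conditional exact p for the group-A total zA given the combined
# total, with nA and nB libraries of equal size. phi = 0 reduces to the
# exact binomial; phi > 0 is negative hypergeometric with shapes
# (nA/phi, nB/phi). Two-sided by summing probabilities <= P(observed).
nb_conditional_p <- function(zA, zB, nA, nB, phi) {
  t <- zA + zB
  if (t == 0) return(1)
  z <- 0:t
  logp <- if (phi == 0) {
    stats::dbinom(z, t, nA / (nA + nB), log = TRUE)
  } else {
    a <- nA / phi
    b <- nB / phi
    lp <- lgamma(z + a) - lgamma(z + 1) + lgamma(t - z + b) - lgamma(t - z + 1)
    lp - max(lp) - log(sum(exp(lp - max(lp))))
  }
  p_obs <- logp[zA + 1]
  min(1, sum(exp(logp[logp <= p_obs + 1e-7])))
}

#' Negative-binomial exact test between two library groups
#'
#' For every gene, tests whether group A's total count differs from group
#' B's, conditional on the combined total, under a negative binomial with
#' the gene's dispersion. Library sizes are treated as equal — counts are
#' expected on a common scale (the upstream normalization fixes each
#' library at one million tags; with raw counts of similar depth the
#' approximation is mild). At `phi = 0` the test is the exact binomial of
#' the group-A total; the two-sided p-value sums the probabilities of all
#' outcomes at most as likely as the observed one. The log2 fold change
#' (A over B) uses group means with a prior count of `prior_count` per
#' library to avoid infinities, and `fdr` is filled by [bh_adjust()].
#'
#' @param counts Wide count tibble.
#' @param group_a,group_b Disjoint character vectors of library ids.
#' @param dispersion A `sage_dispersion` object, or a scalar / per-gene
#'   vector of dispersions.
#' @param prior_count Prior count per library for the fold change
#'   (default 0.125).
#' @param alpha FDR threshold defining the `direction` call (default 0.05).
#' @return A tibble (class `sage_de` added) with `gene_id`, `log2_fc`,
#'   `p_value`, `fdr` and `direction` (`up`/`down`/`ns`, A relative to B).
#' @export
exact_test <- function(counts, group_a, group_b, dispersion,
                       prior_count = 0.125, alpha = 0.05) {
  m <- counts_to_matrix(counts)
  group_a <- intersect(colnames(m), group_a)
  group_b <- intersect(colnames(m), group_b)
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must contain at least one library")
  }
  if (length(intersect(group_a, group_b)) > 0) abort("groups must be disjoint")
  phi <- if (inherits(dispersion, "sage_dispersion")) {
    dispersion$tagwise[rownames(m)]
  } else {
    rep_len(dispersion, nrow(m))
  }
  if (any(is.na(phi))) abort("dispersion missing for some genes")

  nA <- length(group_a)
  nB <- length(group_b)
  zA <- rowSums(m[, group_a, drop = FALSE])
  zB <- rowSums(m[, group_b, drop = FALSE])
  p <- vapply(seq_len(nrow(m)),
              function(g) nb_conditional_p(zA[g], zB[g], nA, nB, phi[g]),
              numeric(1))
  lfc <- log2((zA / nA + prior_count) / (zB / nB + prior_count))
  lfc[zA + zB == 0] <- 0

  out <- tibble(
    gene_id = rownames(m),
    log2_fc = unname(lfc),
    p_value = unname(p),
    fdr = bh_adjust(unname(p))
  ) |>
    mutate(direction = dplyr::case_when(
      .data$fdr < alpha & .data$log2_fc > 0 ~ "up",
      .data$fdr < alpha & .data$log2_fc < 0 ~ "down",
      .default = "ns"
    ))
  class(out) <- c("sage_de", class(out))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating surface over the standard step-up FDR adjustment: monotone
#' enforced, capped at 1, order-equivariant.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Volcano plot of a differential-expression table
#'
#' @param object A `sage_de` tibble from [exact_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sage_de <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$log2_fc, -log10(.data$p_value),
                                       colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(up = "#b2182b", down = "#2166ac", ns = "grey60")
    ) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Classify genes as population-specific or shared responders
#'
#' Given the same contrast tested separately in the two populations,
#' assigns every gene to at most one of: up/down in only one population,
#' or shared (significant in the same direction in both).
#'
#' @param de_lake,de_river DE tibbles over the same gene universe.
#' @param alpha FDR significance threshold (default 0.05).
#' @return A list of class `sage_popsets` of gene-id character vectors:
#'   `lake_only_up`, `lake_only_down`, `river_only_up`, `river_only_down`,
#'   `shared_up`, `shared_down`.
#' @export
classify_population_specific <- function(de_lake, de_river, alpha = 0.05) {
  if (!setequal(de_lake$gene_id, de_river$gene_id)) {
    abort("the two tables must cover the same gene universe")
  }
  de_river <- de_river[match(de_lake$gene_id, de_river$gene_id), ]
  sig_l <- de_lake$fdr < alpha
  sig_r <- de_river$fdr < alpha
  up_l <- sig_l & de_lake$log2_fc > 0
  dn_l <- sig_l & de_lake$log2_fc < 0
  up_r <- sig_r & de_river$log2_fc > 0
  dn_r <- sig_r & de_river$log2_fc < 0
  g <- de_lake$gene_id
  structure(
    list(
      lake_only_up = g[up_l & !sig_r],
      lake_only_down = g[dn_l & !sig_r],
      river_only_up = g[up_r & !sig_l],
      river_only_down = g[dn_r & !sig_l],
      shared_up = g[up_l & up_r],
      shared_down = g[dn_l & dn_r]
    ),
    class = "sage_popsets"
  )
}

#' @export
print.sage_popsets <- function(x, ...) {
  sizes <- vapply(unclass(x), length, integer(1))
  cat("Population-specific DE sets:\n")
  print(sizes)
  invisible(x)
}

#' Pearson chi-squared test of a 2x2 contingency table
#'
#' Without continuity correction, with the p-value from the chi-squared
#' distribution with one degree of freedom. Used to contrast the up/down
#' composition of lake- versus river-specific gene sets.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return A tibble with `chi2`, `df` and `p_value`.
#' @export
chisq_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("`table` must be 2x2")
  if (any(table < 0) || sum(table) == 0) abort("cells must be >= 0 with total > 0")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero row or column margin")
  }
  fit <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble(chi2 = unname(fit$statistic), df = unname(fit$parameter),
         p_value = unname(fit$p.value))
}

#' Mann-Whitney U test
#'
#' U from rank sums with midranks for ties; the p-value is exact (by
#' enumeration) when `nA + nB <= 12` with no ties, otherwise a normal
#' approximation with tie correction. Used for parasite-load contrasts
#' between populations.
#'
#' @param group_a,group_b Numeric vectors (both nonempty).
#' @return A tibble with `u` and `p_value` (two-sided).
#' @export
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be nonempty")
  }
  ties <- any(duplicated(c(group_a, group_b)))
  exact <- (length(group_a) + length(group_b)) <= 12 && !ties
  fit <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = FALSE)
  )
  tibble(u = unname(fit$statistic), p_value = unname(fit$p.value))
}
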