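#' Pearson correlation distance between libraries
#'
#' `d_ij = 1 - r_ij`, with `r` the Pearson correlation of the expression
#' vectors of libraries `i` and `j` over all genes — a scale-free metric
#' well suited to expression profiles, lying in `[0, 2]`. A flag selects
#' the halved variant `(1 - r)/2` in `[0, 1]`.
#'
#' @param counts Wide (normalized) count tibble, `gene_id` + one column
#'   per library.
#' @param halved If `TRUE`, use `(1 - r)/2`.
#' @return A `dist` object labelled with the library ids.
#' @export
correlation_distance <- function(counts, halved = FALSE) {
  m <- counts_to_matrix(counts)
  if (nrow(m) < 2) abort("need >= 2 genes to correlate libraries")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("library with zero expression variance: '",
                 colnames(m)[sds == 0][1], "'"))
  }
  r <- stats::cor(m, method = "pearson")
  d <- 1 - r
  if (halved) d <- d / 2
  stats::as.dist(d)
}

#' Permutational multivariate analysis of variance
#'
#' Partitions the squared-distance structure of a library-by-library
#' distance matrix over a sequence of design factors and tests each term's
#' pseudo-F against a free-permutation null. The machinery is the standard
#' one: the Gower-centred inner-product matrix `G = -(1/2) C D2 C` is
#' decomposed by sequential (Type I) hat-matrix projections of the
#' cumulative design, so `SS(term_j) = tr(H_j G) - tr(H_{j-1} G)` and
#' `pseudo-F = (SS_term/df_term) / (SS_res/df_res)`. Family labels are
#' unique within population, so listing `family` after `population` yields
#' the nested coding (2 extra df for 4 families in 2 populations). The
#' permutation p-value is `(#\{F* >= F\} + 1) / (n_permutations + 1)`.
#'
#' @param dist A `dist` object (e.g. from [correlation_distance()]) with
#'   labels matching `design$library_id`.
#' @param design Library design tibble.
#' @param terms Ordered character vector of design columns to fit.
#' @param n_permutations Number of free permutations of library labels
#'   (default 999).
#' @param seed Integer seed; the same seed reproduces the p-values.
#' @return An object of class `sage_permanova`; see [tidy.sage_permanova()].
#' @export
permanova <- function(dist, design,
                      terms = c("treatment", "population", "family", "sex"),
                      n_permutations = 999L, seed = NULL) {
  check_scalar_int(n_permutations, "n_permutations", min = 1)
  d <- as.matrix(dist)
  n <- nrow(d)
  labs <- labels(dist) %||% rownames(d)
  if (!is.null(labs) && all(labs %in% design$library_id)) {
    design <- design[match(labs, design$library_id), , drop = FALSE]
  }
  if (nrow(design) != n) abort("`design` does not match the distance matrix")
  missing_terms <- setdiff(terms, names(design))
  if (length(missing_terms) > 0) {
    abort(paste0("term not in design: '", missing_terms[1], "'"))
  }

  # Gower-centred inner products from squared distances
  A <- -0.5 * d^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C

  # cumulative hat matrices (intercept first)
  X <- matrix(1, n, 1)
  hats <- list(hat_matrix(X))
  df <- integer(length(terms))
  for (j in seq_along(terms)) {
    Xj <- stats::model.matrix(~ 0 + factor(design[[terms[j]]]))
    X <- cbind(X, Xj)
    H <- hat_matrix(X)
    df[j] <- as.integer(round(sum(diag(H)) - sum(diag(hats[[j]]))))
    if (df[j] <= 0) {
      abort(paste0("term '", terms[j],
                   "' is confounded with earlier terms (adds no df)"))
    }
    hats[[j + 1]] <- H
  }
  df_res <- n - as.integer(round(sum(diag(hats[[length(hats)]]))))
  if (df_res <= 0) abort("no residual degrees of freedom")

  term_stats <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    ss <- diff(tr)
    ss_res <- sum(diag(Gp)) - tr[length(tr)]
    f <- (ss / df) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- term_stats(G)

  exceed <- numeric(length(terms))
  with_seed_if(seed, {
    for (b in seq_len(n_permutations)) {
      p <- sample.int(n)
      fp <- term_stats(G[p, p, drop = FALSE])$f
      exceed <- exceed + (fp >= obs$f - 1e-12)
    }
  })
  pval <- (exceed + 1) / (n_permutations + 1)

  structure(
    list(
      table = tibble(
        term = terms, df = df, ss = obs$ss,
        f = obs$f, p_value = pval
      ),
      df_residual = df_res,
      ss_residual = obs$ss_res,
      ss_total = sum(diag(G)),
      n = n,
      n_permutations = as.integer(n_permutations),
      seed = seed
    ),
    class = "sage_permanova"
  )
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' @export
print.sage_permanova <- function(x, ...) {
  cat("PerMANOVA (", x$n_permutations, " free permutations)\n", sep = "")
  tab <- x$table
  tab$df <- paste0(tab$df, "/", x$df_residual)
  print(as.data.frame(tab), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @rdname permanova
#' @param x A `sage_permanova` object.
#' @param ... Unused.
#' @export
tidy.sage_permanova <- function(x, ...) {
  x$table |>
    mutate(df_residual = x$df_residual) |>
    relocate("df_residual", .after = "df")
}

#' @rdname permanova
#' @export
glance.sage_permanova <- function(x, ...) {
  tibble(
    n = x$n, n_permutations = x$n_permutations,
    ss_total = x$ss_total, ss_residual = x$ss_residual,
    r_squared = 1 - x$ss_residual / x$ss_total
  )
}

#' Nonmetric multidimensional scaling of a distance matrix
#'
#' Kruskal-style NMDS minimizing stress-1 (monotone regression of
#' configuration distances on dissimilarity ranks, primary treatment of
#' ties), run from a classical-scaling start plus `n_starts - 1` random
#' starts; the configuration with the lowest stress is kept.
#'
#' @param dist A `dist` object.
#' @param dims Embedding dimension (default 2; must be < n - 1).
#' @param n_starts Number of starts (>= 1).
#' @param max_iter Maximum iterations per start.
#' @param seed Integer seed; same seed, same coordinates.
#' @return An object of class `sage_nmds` with elements `points` (tibble
#'   `library_id`, `NMDS1`, ...), `stress` (stress-1, a fraction), `dims`,
#'   `n_starts`, `seed`.
#' @export
nmds <- function(dist, dims = 2L, n_starts = 20L, max_iter = 200L,
                 seed = NULL) {
  check_scalar_int(dims, "dims", min = 1)
  check_scalar_int(n_starts, "n_starts", min = 1)
  d <- stats::as.dist(dist)
  if (any(!is.finite(d))) abort("non-finite distances")
  n <- attr(d, "Size")
  if (dims >= n - 1) abort("`dims` must be < number of libraries - 1")

  with_seed_if(seed, {
    init <- stats::cmdscale(d, k = dims)
    if (ncol(init) < dims) {
      init <- cbind(init, matrix(stats::rnorm(n * (dims - ncol(init)), sd = 1e-4),
                                 n, dims - ncol(init)))
    }
    best <- NULL
    for (s in seq_len(n_starts)) {
      y0 <- if (s == 1) init else matrix(stats::rnorm(n * dims), n, dims)
      fit <- vegan::monoMDS(d, y = y0, k = dims, model = "global",
                            maxit = max_iter)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    pts <- best$points
    colnames(pts) <- paste0("NMDS", seq_len(dims))
    structure(
      list(
        points = dplyr::bind_cols(
          tibble(library_id = labels(d) %||% as.character(seq_len(n))),
          as_tibble(pts)
        ),
        stress = best$stress,
        dims = as.integer(dims),
        n_starts = as.integer(n_starts),
        seed = seed
      ),
      class = "sage_nmds"
    )
  })
}

#' @export
print.sage_nmds <- function(x, ...) {
  cat("NMDS:", nrow(x$points), "libraries in", x$dims,
      "dimensions; stress-1 =", signif(x$stress, 3), "\n")
  invisible(x)
}

#' @rdname nmds
#' @param x A `sage_nmds` object.
#' @param ... Unused.
#' @export
tidy.sage_nmds <- function(x, ...) x$points

#' @rdname nmds
#' @export
glance.sage_nmds <- function(x, ...) {
  tibble(stress = x$stress, dims = x$dims, n_starts = x$n_starts)
}

#' Ordination plot of an NMDS fit
#'
#' @param object A `sage_nmds` object.
#' @param design Optional design tibble joined on `library_id`; when given,
#'   points are coloured by population and shaped by treatment.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sage_nmds <- function(object, design = NULL, ...) {
  pts <- object$points
  if (!is.null(design)) pts <- left_join(pts, design, by = "library_id")
  aes <- if (!is.null(design)) {
    ggplot2::aes(.data$NMDS1, .data$NMDS2, colour = .data$population,
                 shape = .data$treatment)
  } else {
    ggplot2::aes(.data$NMDS1, .data$NMDS2)
  }
  ggplot2::ggplot(pts, aes) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      subtitle = paste0("stress = ", signif(object$stress, 2))
    ) +
    ggplot2::theme_minimal()
}
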