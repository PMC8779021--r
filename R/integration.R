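#' Canonical reactor-level variable names
#'
#' The nine per-reactor variables integrated by the PCA stage: organic-matter
#' removal (TOC), cumulative methane (CH4) and carbon dioxide (CO2)
#' production, ecotoxicity on green algae (Ecotox), esterase (EST),
#' glutathione-S-transferase (GST) and catalase (CAT) activities, reactive
#' oxygen species generation (ROS), and the fraction of non-viable cells
#' (Nonviable).
#' @export
reactor_variables <- c("TOC", "CH4", "CO2", "Ecotox", "EST", "GST", "CAT",
                       "ROS", "Nonviable")

as_metrics_matrix <- function(metrics) {
  if (is.data.frame(metrics)) {
    if ("reactor" %in% names(metrics)) {
      rn <- as.character(metrics$reactor)
      metrics <- metrics[, setdiff(names(metrics), "reactor"), drop = FALSE]
      m <- as.matrix(metrics)
      rownames(m) <- rn
    } else {
      m <- as.matrix(metrics)
    }
  } else {
    m <- as.matrix(metrics)
  }
  if (!is.numeric(m)) stop("reactor metrics must be numeric", call. = FALSE)
  if (anyNA(m))
    stop("reactor metrics contain missing cells; PCA requires a complete matrix",
         call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("R", seq_len(nrow(m)))
  m
}

#' Read a reactor-metrics table
#'
#' CSV with one row per reactor. A `reactor` id column plus the nine
#' variables in [reactor_variables] is expected (exact header match,
#' column order free).
#'
#' @param path CSV path.
#' @return numeric matrix, reactors in rows, named variables in columns.
#' @export
read_reactor_metrics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("reactor", reactor_variables), names(df))
  if (length(miss))
    stop("reactor metrics CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  as_metrics_matrix(df[, c("reactor", reactor_variables)])
}

#' Z-score standardize reactor metrics
#'
#' Centers each variable to mean 0 and scales it to unit standard deviation
#' (n-1 denominator), putting the nine heterogeneous-unit variables on a
#' common scale before PCA.
#'
#' @param metrics numeric matrix or data.frame (optionally with a `reactor`
#'   id column), reactors in rows.
#' @return standardized numeric matrix of the same shape.
#' @examples
#' zscore_metrics(cbind(a = c(1, 2, 3), b = c(10, 30, 20)))
#' @export
zscore_metrics <- function(metrics) {
  m <- as_metrics_matrix(metrics)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0]
    stop("cannot z-score constant column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  z <- scale(m, center = TRUE, scale = sds)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

#' Correlation-matrix PCA of standardized reactor metrics
#'
#' Principal component analysis on z-scored variables, i.e. the
#' eigendecomposition of their correlation matrix; eigenvalues over the full
#' decomposition sum to the number of variables. A deterministic sign
#' convention is applied (the largest-magnitude element of each loading
#' column is positive), since the orientation of each axis is otherwise
#' arbitrary.
#'
#' @param metrics reactor metrics (raw or already standardized; see
#'   `standardize`).
#' @param k number of components to retain (default 2); must satisfy
#'   `k <= min(nrow - 1, ncol)`.
#' @param standardize z-score the input first (default `TRUE`; set to
#'   `FALSE` if `metrics` is already standardized).
#' @return an object of class `reactor_pca`: list with `eigenvalues` (all
#'   components, descending), `variance_explained` (fractions of total),
#'   `loadings` (variables x k), `scores` (reactors x k), `k`, `n_variables`.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(54), 6, 9, dimnames = list(NULL, reactor_variables))
#' p <- reactor_pca(m)
#' sum(p$variance_explained[1:2])
#' @export
reactor_pca <- function(metrics, k = 2L, standardize = TRUE) {
  z <- if (standardize) zscore_metrics(metrics) else as_metrics_matrix(metrics)
  n <- nrow(z)
  p <- ncol(z)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > min(n - 1L, p))
    stop("'k' must be an integer in [1, min(#reactors - 1, #variables)]",
         call. = FALSE)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  eig <- pc$sdev^2
  load <- pc$rotation
  scores <- pc$x
  # sign convention: largest-|.| element of each loading column positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(eigenvalues = eig,
         variance_explained = eig / sum(eig),
         loadings = load[, seq_len(k), drop = FALSE],
         scores = scores[, seq_len(k), drop = FALSE],
         k = k, n_variables = p),
    class = "reactor_pca"
  )
}

#' @export
print.reactor_pca <- function(x, ...) {
  cat(sprintf(
    "reactor_pca: %d variables, k = %d; eigenvalues %s; PC1+..+PC%d explain %.1f%% of variance\n",
    x$n_variables, x$k,
    paste(sprintf("%.3g", x$eigenvalues[seq_len(x$k)]), collapse = ", "),
    x$k, 100 * sum(x$variance_explained[seq_len(x$k)])))
  invisible(x)
}

#' Biplot table: variable arrows and reactor points
#'
#' Tidy coordinates for a 2-component biplot: variable arrows are the
#' loading columns scaled by the square root of their eigenvalue
#' (correlation-scaled arrows), reactor points are the scores.
#'
#' @param result a [reactor_pca()] with `k = 2`.
#' @return data.frame with columns `type` (`"variable"`/`"reactor"`),
#'   `name`, `x`, `y`.
#' @export
biplot_table <- function(result) {
  stopifnot(inherits(result, "reactor_pca"))
  if (result$k != 2L)
    stop("biplot_table() requires a 2-component result (k = 2)",
         call. = FALSE)
  sc <- sqrt(result$eigenvalues[1:2])
  arrows <- sweep(result$loadings, 2, sc, `*`)
  rbind(
    data.frame(type = "variable", name = rownames(arrows),
               x = arrows[, 1], y = arrows[, 2], stringsAsFactors = FALSE),
    data.frame(type = "reactor", name = rownames(result$scores),
               x = result$scores[, 1], y = result$scores[, 2],
               stringsAsFactors = FALSE),
    make.row.names = FALSE
  )
}

#' Pairwise reactor distances in score space
#'
#' Euclidean distances between reactor scores on the retained components;
#' reported so the user can judge reactor groupings, which are interpretive
#' rather than algorithmic.
#'
#' @param result a [reactor_pca()].
#' @return a `dist` object.
#' @export
score_distances <- function(result) {
  stopifnot(inherits(result, "reactor_pca"))
  stats::dist(result$scores)
}

#' Simulate reactor metrics from a planted two-factor model
#'
#' Generates an n x 9 reactor-metrics matrix from two latent factors with a
#' loading structure mirroring the observed variable groupings: TOC, CH4 and
#' EST load positively and Ecotox and Nonviable negatively on factor 1; CO2
#' and ROS load positively and CAT and GST negatively on factor 2. With the
#' default squared loadings (0.9225 on factor 1, 0.35 on factor 2) the
#' planted correlation matrix has leading eigenvalues exactly
#' `1 + 4 * 0.9225 = 4.69` and `1 + 3 * 0.35 = 2.05`, i.e. the two factors
#' carry about 52% and 23% of the variance.
#'
#' In `exact = TRUE` mode (default) factor scores and residuals are
#' orthogonalized and rescaled so the sample covariance equals the planted
#' covariance exactly and PCA recovers the planted eigenvalues
#' deterministically; with `exact = FALSE` plain normal draws are used and
#' recovery is subject to sampling noise. `exact` mode requires
#' `n_reactors >= 12`.
#'
#' @param n_reactors number of simulated reactors (rows).
#' @param f1_load2,f2_load2 squared loadings of the factor-1 and factor-2
#'   variable blocks.
#' @param exact orthogonalize scores/residuals (see Details).
#' @param seed integer seed.
#' @return numeric matrix with an attribute `planted` (list with
#'   `eigenvalues` of the planted correlation matrix and `share2`, the
#'   planted two-component variance share).
#' @export
simulate_reactor_metrics <- function(n_reactors = 24L, f1_load2 = 0.9225,
                                     f2_load2 = 0.35, exact = TRUE,
                                     seed = 1L) {
  n <- as.integer(n_reactors)
  p <- 9L
  L <- matrix(0, p, 2, dimnames = list(reactor_variables, NULL))
  L[c("TOC", "CH4", "EST"), 1] <- sqrt(f1_load2)
  L[c("Ecotox", "Nonviable"), 1] <- -sqrt(f1_load2)
  L[c("CO2", "ROS"), 2] <- sqrt(f2_load2)
  L[c("CAT", "GST"), 2] <- -sqrt(f2_load2)
  psi <- 1 - rowSums(L^2)
  if (any(psi <= 0))
    stop("squared loadings must be < 1 so unique variances stay positive",
         call. = FALSE)
  C <- L %*% t(L) + diag(psi)
  planted_eig <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
                      decreasing = TRUE)
  X <- with_seed(seed, {
    if (exact) {
      if (n < 2L + p + 1L)
        stop("exact mode needs at least ", 2L + p + 1L, " reactors",
             call. = FALSE)
      raw <- cbind(1, matrix(stats::rnorm(n * (2L + p)), n))
      Q <- qr.Q(qr(raw))
      FF <- Q[, 2:3, drop = FALSE] * sqrt(n - 1)
      E <- Q[, 4:(3L + p), drop = FALSE] %*% diag(sqrt(psi)) * sqrt(n - 1)
      FF %*% t(L) + E
    } else {
      FF <- matrix(stats::rnorm(n * 2), n)
      E <- matrix(stats::rnorm(n * p), n) %*% diag(sqrt(psi))
      FF %*% t(L) + E
    }
  })
  colnames(X) <- reactor_variables
  rownames(X) <- sprintf("R%02d", seq_len(n))
  attr(X, "planted") <- list(eigenvalues = planted_eig,
                             share2 = sum(planted_eig[1:2]) / p)
  X
}
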