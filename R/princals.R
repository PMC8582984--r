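#' Optimal-scaling categorical PCA (princals-style alternating least squares)
#'
#' Performs categorical principal component analysis in the Gifi tradition:
#' each categorical variable j is replaced by a quantified version
#' `h_j = G_j y_j` (indicator matrix times category quantifications,
#' standardized to mean 0, variance 1), and the algorithm alternates between
#' (a) a rank-`ndim` least-squares fit of the quantified data matrix H —
#' object scores `X` (normalized `X'X = n I`) and loadings `A`, obtained
#' from the SVD of H, so the solution sits in principal-axes orientation —
#' and (b) re-quantification of every variable: the optimal unrestricted
#' quantification is the vector of category means of the variable's fitted
#' values `X a_j`, to which the scaling-level restriction is applied
#' (`nominal`: none; `ordinal`: monotone in the category order, either
#' direction, via weighted pool-adjacent-violators; `numeric`: linear in the
#' category values). Both half-steps minimize the same least-squares loss
#' `sum_j ||h_j - X a_j||^2 / (n m)`, so the loss is non-increasing.
#'
#' Variance accounted for (VAF) by component s is `d_s^2 / (n m)` (singular
#' values of the final H), i.e. the share of the total variance of the m
#' standardized quantified variables. With all-numeric scaling H is just the
#' standardized data matrix and the VAF shares equal the eigenvalue shares
#' of classical PCA on the correlation matrix.
#'
#' @param data matrix or data frame of categorical variables (numeric codes
#'   or factors). Every variable needs at least 2 observed categories.
#' @param ndim number of components p (1 <= p <= m, p < n)
#' @param level scaling level, `"ordinal"` (default), `"nominal"` or
#'   `"numeric"`; a single value or one per variable. Ordinal order is the
#'   sort order of numeric codes (or factor level order); numeric level
#'   requires numeric category values.
#' @param tol convergence tolerance on the loss decrease per iteration
#' @param max_iter maximum number of ALS iterations
#' @param seed integer seed for the random initial quantifications
#' @param verbose print the loss every 25 iterations
#' @return object of class `princals_fit`: `scores` (n x p object scores,
#'   `X'X = n I`), `loadings` (m x p; component correlations of the
#'   quantified variables), `quantifications` (per variable, a data frame of
#'   category, count, quantification), `vaf` (per-component variance share,
#'   non-increasing), `lambda` (component variances), `loss` (per-iteration
#'   trace), `converged`, `level`, `ndim`, `n`, `m`.
#' @export
fit_princals <- function(data, ndim = 2L, level = "ordinal", tol = 1e-6,
                         max_iter = 500L, seed = 0L, verbose = FALSE) {
  data <- as.data.frame(data, optional = TRUE)
  n <- nrow(data)
  m <- ncol(data)
  .assert(m >= 1 && n >= 2, "need at least 2 rows and 1 variable")
  .assert(ndim >= 1 && ndim <= m && ndim < n,
          "`ndim` must satisfy 1 <= ndim <= n_variables and ndim < n")
  .assert(tol > 0, "`tol` must be positive")
  level <- rep_len(match.arg(level, c("ordinal", "nominal", "numeric"),
                             several.ok = TRUE), m)
  if (is.null(names(data))) names(data) <- paste0("V", seq_len(m))

  vars <- lapply(seq_len(m), function(j) {
    v <- data[[j]]
    if (anyNA(v)) stop("variable ", names(data)[j], " has missing values",
                       call. = FALSE)
    f <- factor(v)
    if (nlevels(f) < 2)
      stop("constant variable: ", names(data)[j], call. = FALSE)
    vals <- suppressWarnings(as.numeric(levels(f)))
    if (level[j] %in% c("ordinal", "numeric") && anyNA(vals)) {
      if (level[j] == "numeric")
        stop("variable ", names(data)[j],
             ": numeric level needs numeric category values", call. = FALSE)
      vals <- seq_len(nlevels(f))  # ordinal on factor level order
    }
    g <- as.integer(f)
    list(g = g, k = nlevels(f), labels = levels(f), values = vals,
         counts = tabulate(g, nlevels(f)))
  })

  standardize_quant <- function(y, var) {
    # weighted centering/scaling so h = y[g] has mean 0 and variance 1
    d <- var$counts
    y <- y - sum(d * y) / n
    ssq <- sum(d * y^2)
    if (ssq < .Machine$double.eps) return(NULL)  # degenerate quantification
    y * sqrt(n / ssq)
  }

  # initial quantifications: category values plus a little seeded jitter,
  # which breaks ties for nominal variables and varies the start by seed
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  quants <- lapply(seq_len(m), function(j) {
    var <- vars[[j]]
    base <- if (anyNA(var$values)) seq_len(var$k) else var$values
    if (level[j] == "numeric") return(standardize_quant(base, var))  # exact, fixed
    y <- standardize_quant(base + stats::rnorm(var$k, sd = 0.05), var)
    if (is.null(y)) y <- standardize_quant(seq_len(var$k) + stats::rnorm(var$k, sd = 0.05), var)
    y
  })
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv)

  H <- vapply(seq_len(m), function(j) quants[[j]][vars[[j]]$g], numeric(n))
  loss_trace <- numeric(0)
  loss_prev <- Inf
  converged <- FALSE
  sv <- NULL

  for (iter in seq_len(max_iter)) {
    Hc <- H - matrix(colMeans(H), n, m, byrow = TRUE)
    sv <- svd(Hc, nu = ndim, nv = ndim)
    X <- sqrt(n) * sv$u
    A <- sv$v %*% diag(sv$d[seq_len(ndim)] / sqrt(n), ndim)
    loss <- 1 - sum(sv$d[seq_len(ndim)]^2) / (n * m)
    loss_trace <- c(loss_trace, loss)
    if (verbose && iter %% 25L == 0L)
      message(sprintf("iter %d  loss %.8f", iter, loss))
    if (loss_prev - loss < tol) { converged <- TRUE; break }
    loss_prev <- loss

    fitted <- X %*% t(A)  # rank-p reconstruction; target for re-quantification
    for (j in seq_len(m)) {
      if (level[j] == "numeric") next  # linear quantification is fixed
      var <- vars[[j]]
      y_hat <- as.numeric(rowsum(fitted[, j], var$g, reorder = TRUE)) / var$counts
      if (level[j] == "ordinal") y_hat <- monotone_quantification(y_hat, var$counts)
      y <- standardize_quant(y_hat, var)
      if (is.null(y)) next  # keep previous quantification when degenerate
      quants[[j]] <- y
      H[, j] <- y[var$g]
    }
  }

  lambda <- sv$d[seq_len(ndim)]^2 / n
  X <- sqrt(n) * sv$u
  A <- sv$v %*% diag(sv$d[seq_len(ndim)] / sqrt(n), ndim)
  dimnames(X) <- list(rownames(data), paste0("D", seq_len(ndim)))
  dimnames(A) <- list(names(data), paste0("D", seq_len(ndim)))
  qtabs <- lapply(seq_len(m), function(j)
    data.frame(category = vars[[j]]$labels, count = vars[[j]]$counts,
               quantification = quants[[j]], stringsAsFactors = FALSE))
  names(qtabs) <- names(data)
  structure(list(scores = X, loadings = A, quantifications = qtabs,
                 vaf = lambda / m, lambda = lambda, loss = loss_trace,
                 converged = converged, level = level, ndim = as.integer(ndim),
                 n = n, m = m),
            class = "princals_fit")
}

# Weighted pool-adjacent-violators; fits the best monotone (isotonic or
# antitonic, whichever has smaller weighted SSE) quantification.
monotone_quantification <- function(y, w) {
  up <- pava(y, w)
  dn <- -pava(-y, w)
  if (sum(w * (y - up)^2) <= sum(w * (y - dn)^2)) up else dn
}

pava <- function(y, w) {
  k <- length(y)
  if (k == 1) return(y)
  val <- y; wt <- w; idx <- rep(1L, k)  # idx: block id per original position
  # classic stack-based PAVA
  vals <- numeric(k); wts <- numeric(k); sizes <- integer(k); top <- 0L
  for (i in seq_len(k)) {
    top <- top + 1L
    vals[top] <- y[i]; wts[top] <- w[i]; sizes[top] <- 1L
    while (top > 1L && vals[top - 1L] > vals[top]) {
      merged_w <- wts[top - 1L] + wts[top]
      vals[top - 1L] <- (wts[top - 1L] * vals[top - 1L] + wts[top] * vals[top]) / merged_w
      wts[top - 1L] <- merged_w
      sizes[top - 1L] <- sizes[top - 1L] + sizes[top]
      top <- top - 1L
    }
  }
  rep(vals[seq_len(top)], sizes[seq_len(top)])
}

#' @export
print.princals_fit <- function(x, ...) {
  cat("<princals_fit> n =", x$n, " variables =", x$m, " ndim =", x$ndim, "\n")
  cat("  converged:", x$converged, "after", length(x$loss), "iterations; loss",
      format(x$loss[length(x$loss)], digits = 6), "\n")
  cat("  VAF (first components):",
      paste(format(100 * utils::head(x$vaf, 5), digits = 3), collapse = "% "),
      "%\n")
  invisible(x)
}

#' Select leading components by cumulative variance
#'
#' Keeps the smallest number k of leading components whose cumulative VAF
#' reaches the threshold (inclusive), mirroring the study's rule of keeping
#' the components that describe 80 percent of the variance.
#'
#' @param fit a `princals_fit`
#' @param variance_threshold fraction in (0, 1]
#' @param scaling `"principal"` (default) returns the retained components in
#'   principal coordinates — object scores scaled so each column has
#'   variance `lambda_s`, like classical PCA scores — so downstream
#'   similarities weight every component by the variance it explains;
#'   `"uniform"` returns the raw sphered object-score columns (`X'X = nI`).
#' @return the n x k matrix of retained component scores, with the selected
#'   `k` and the cumulative VAF attached as attributes `k` and
#'   `cumulative_vaf`.
#' @export
select_components <- function(fit, variance_threshold = 0.8,
                              scaling = c("principal", "uniform")) {
  .assert(inherits(fit, "princals_fit"), "`fit` must be a princals_fit")
  .assert(variance_threshold > 0 && variance_threshold <= 1,
          "`variance_threshold` must be in (0, 1]")
  scaling <- match.arg(scaling)
  cum <- cumsum(fit$vaf)
  reach <- which(cum >= variance_threshold - 1e-12)
  if (length(reach) == 0)
    stop(sprintf(paste0("cumulative VAF of the %d fitted components is %.3f, ",
                        "below the %.2f threshold; refit with a larger ndim"),
                 fit$ndim, cum[length(cum)], variance_threshold), call. = FALSE)
  k <- reach[1]
  out <- fit$scores[, seq_len(k), drop = FALSE]
  if (scaling == "principal")
    out <- out %*% diag(sqrt(fit$lambda[seq_len(k)]), k)
  attr(out, "k") <- k
  attr(out, "cumulative_vaf") <- cum[k]
  out
}
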