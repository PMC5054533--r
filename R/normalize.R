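## Jacobian-penalized profile negative log-likelihood of the arsinh-affine
## model, over par = c(a_1..a_S, log b_1..log b_S) for an anchor matrix M.
## -sum log h' = N log(ln2) + n_rows sum(log b_s) + 0.5 sum log(1+u^2)
.glog_objective <- function(par, M) {
  S <- ncol(M)
  ln2 <- log(2)
  a <- par[1:S]; logb <- par[(S + 1):(2 * S)]; b <- exp(logb)
  u <- sweep(sweep(M, 2, a, "-"), 2, b, "/")
  y <- asinh(u) / ln2
  rss <- sum((y - rowMeans(y))^2)
  N <- length(M)
  (N / 2) * log(max(rss, 1e-300) / N) +
    N * log(ln2) + nrow(M) * sum(logb) + 0.5 * sum(log1p(u^2))
}

.glog_gradient <- function(par, M) {
  S <- ncol(M)
  ln2 <- log(2)
  a <- par[1:S]; logb <- par[(S + 1):(2 * S)]; b <- exp(logb)
  u <- sweep(sweep(M, 2, a, "-"), 2, b, "/")
  y <- asinh(u) / ln2
  r <- y - rowMeans(y)
  rss <- max(sum(r^2), 1e-300)
  N <- length(M)
  w <- 1 / sqrt(1 + u^2)
  ## dy/da_s = -w/(ln2 b_s); dy/dlogb_s = -u w / ln2
  g_rss_a <- -(N / rss) * colSums(r * w) / (ln2 * b)
  g_rss_lb <- -(N / rss) * colSums(r * u * w) / ln2
  g_jac_a <- -colSums(u * w^2) / b
  g_jac_lb <- nrow(M) - colSums(u^2 * w^2)
  c(g_rss_a + g_jac_a, g_rss_lb + g_jac_lb)
}

#' Fit the arsinh-affine variance-stabilizing calibration
#'
#' Estimates one affine pair (offset `a_s`, scale `b_s > 0`) per sample
#' column so that the generalized-log transform
#' \deqn{y_{ps} = \operatorname{arsinh}\!\big((x_{ps} - a_s)/b_s\big)/\ln 2}
#' makes anchor peptides (spike-in material added in equal amounts to every
#' channel, hence carrying only technical variation) as constant across
#' samples as possible. The fit minimizes the Jacobian-penalized profile
#' negative log-likelihood
#' \deqn{L(a, b) = \tfrac{N}{2}\ln(\mathrm{RSS}/N) - \sum_{p,s} \ln h'_s(x_{ps}),}
#' with \eqn{\mathrm{RSS} = \sum_{p,s} (y_{ps} - \bar y_p)^2} and
#' \eqn{h'_s(x) = 1/(\ln 2\, b_s \sqrt{1 + u_{ps}^2})},
#' \eqn{u_{ps} = (x_{ps} - a_s)/b_s}. The Jacobian term makes the problem
#' identifiable (the bare least-squares objective is degenerate as
#' \eqn{b \to \infty}). Optimization is quasi-Newton (BFGS) over
#' \eqn{\{a_s, \log b_s\}} with an analytic gradient; the log-parameterization
#' enforces positivity of the scales.
#'
#' An optional least-trimmed-squares mode (`trim_fraction < 1`) iteratively
#' refits on the rows with the smallest residual sums, for self-calibration
#' on endogenous peptides where outliers are expected; spike anchors are
#' assumed clean (default `trim_fraction = 1`).
#'
#' @param anchor a raw-scale complete-case `peptide_matrix` (or bare matrix).
#' @param trim_fraction fraction of rows retained in the trimmed fit.
#' @param max_iter maximum BFGS iterations.
#' @param tol convergence tolerance on the gradient norm.
#' @param min_peptides minimum number of anchor rows required.
#' @return a `normalization_model`: list with `samples`, `a`, `b`,
#'   `objective`, `converged`, `iterations`, `gradient_norm`.
#' @export
fit_stabilizer <- function(anchor, trim_fraction = 1, max_iter = 500,
                           tol = 1e-3, min_peptides = 10) {
  X <- if (inherits(anchor, "peptide_matrix")) anchor$values else anchor
  if (any(is.na(X))) stop("anchor must be complete-case (no missing values)")
  S <- ncol(X)
  if (S < 2) stop("anchor must have at least 2 samples")
  if (nrow(X) < min_peptides) {
    stop("anchor-too-small error: ", nrow(X), " peptides < floor of ",
         min_peptides)
  }
  if (trim_fraction <= 0 || trim_fraction > 1) {
    stop("trim_fraction must lie in (0, 1]")
  }

  ln2 <- log(2)
  objective <- .glog_objective
  gradient <- .glog_gradient

  init <- function(M) {
    madx <- apply(M, 2, stats::mad)
    madx[madx <= 0] <- 1
    b0 <- madx / exp(mean(log(madx)))
    c(rep(0, S), log(b0))
  }

  fit_once <- function(M) {
    par0 <- init(M)
    ## degenerate zero-residual anchor: already perfectly calibrated at init
    a0 <- par0[1:S]; b0 <- exp(par0[(S + 1):(2 * S)])
    y0 <- asinh(sweep(sweep(M, 2, a0, "-"), 2, b0, "/")) / ln2
    if (sum((y0 - rowMeans(y0))^2) < 1e-12 * length(M)) {
      return(list(par = par0, value = -Inf, counts = 0L, degenerate = TRUE))
    }
    opt <- stats::optim(par0, objective, gradient, M = M, method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-12))
    list(par = opt$par, value = opt$value, counts = opt$counts[["function"]],
         degenerate = FALSE)
  }

  M <- X
  fit <- fit_once(M)
  if (trim_fraction < 1 && !fit$degenerate) {
    for (it in 1:3) {
      a <- fit$par[1:S]; b <- exp(fit$par[(S + 1):(2 * S)])
      y <- asinh(sweep(sweep(X, 2, a, "-"), 2, b, "/")) / ln2
      row_rss <- rowSums((y - rowMeans(y))^2)
      keep <- order(row_rss)[seq_len(max(min_peptides,
                                         floor(trim_fraction * nrow(X))))]
      M <- X[sort(keep), , drop = FALSE]
      fit <- fit_once(M)
    }
  }

  gn <- if (fit$degenerate) 0 else sqrt(sum(gradient(fit$par, M)^2))
  structure(
    list(samples = colnames(X), a = stats::setNames(fit$par[1:S], colnames(X)),
         b = stats::setNames(exp(fit$par[(S + 1):(2 * S)]), colnames(X)),
         objective = fit$value,
         ## relative gradient criterion: the objective is extensive in the
         ## number of anchor cells, so the gradient norm is judged against it
         converged = fit$degenerate || gn < tol * max(1, abs(fit$value)),
         iterations = fit$counts, gradient_norm = gn,
         n_anchor = nrow(M)),
    class = "normalization_model"
  )
}

#' @export
print.normalization_model <- function(x, ...) {
  cat("normalization_model over", length(x$b), "samples; converged:",
      x$converged, "\n")
  cat("  scale range b:", signif(range(x$b), 4), " offset range a:",
      signif(range(x$a), 4), "\n")
  invisible(x)
}

#' Apply a fitted calibration to a raw peptide matrix
#'
#' Transforms every raw value by the generalized log
#' `y = arsinh((x - a_s)/b_s) / ln 2`. High-intensity values approximate
#' log2 intensities; values at or below the fitted background remain finite
#' (the transform is defined on the whole real line). Missing values stay
#' missing.
#'
#' @param matrix a raw-scale `peptide_matrix`.
#' @param model a `normalization_model` covering all matrix samples.
#' @return the matrix on the stabilized scale (`scale = "glog2"`).
#' @export
apply_stabilizer <- function(matrix, model) {
  X <- matrix$values
  miss <- setdiff(colnames(X), model$samples)
  if (length(miss)) {
    stop("model-mismatch error: no calibration parameters for sample(s) ",
         paste(miss, collapse = ", "))
  }
  a <- model$a[colnames(X)]
  b <- model$b[colnames(X)]
  Y <- asinh(sweep(sweep(X, 2, a, "-"), 2, b, "/")) / log(2)
  structure(list(values = Y, protein = matrix$protein, scale = "glog2"),
            class = "peptide_matrix")
}

#' Row-median centering to relative log2 expression
#'
#' Subtracts from each row its across-sample median (over observed entries),
#' giving the abundance of each sample relative to the median across all
#' samples per gene/peptide. Rows with no observed value are dropped.
#'
#' @param matrix a numeric matrix (features x samples) or `peptide_matrix`.
#' @return a matrix of the same shape (minus all-missing rows).
#' @export
median_center <- function(matrix) {
  X <- if (inherits(matrix, "peptide_matrix")) matrix$values else matrix
  keep <- rowSums(!is.na(X)) > 0
  X <- X[keep, , drop = FALSE]
  X - apply(X, 1, stats::median, na.rm = TRUE)
}

#' Serialize a normalization model to TSV (+ JSON diagnostics sidecar)
#' @param model a `normalization_model`.
#' @param path output TSV path; diagnostics go to `<path>.json`.
#' @export
write_normalization_model <- function(model, path) {
  utils::write.table(
    data.frame(sample = model$samples, a = model$a, b = model$b),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(objective = model$objective, converged = model$converged,
         iterations = model$iterations, gradient_norm = model$gradient_norm,
         n_anchor = model$n_anchor),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
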