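#' Fit the animal model by REML through Henderson's mixed-model equations
#'
#' Fits `y = Xb + Zu + e` with `u ~ N(0, A sigma_a2)` and
#' `e ~ N(0, I sigma_e2)`, where X holds an intercept, herd-year-season
#' class effects, a calving-age covariate, and (optionally) the tested
#' genotype or haplotype-combination factor. The REML log-likelihood is
#' profiled down to the single variance ratio `lambda = sigma_e2 / sigma_a2`:
#' at each `lambda` Henderson's equations
#' `[X'X  X'Z; Z'X  Z'Z + lambda * Ainv]` are solved by sparse Cholesky,
#' `sigma_e2` has a closed form, and the profile is minimised over
#' `log(lambda)` by golden-section search with parabolic (Brent) refinement.
#'
#' @param data Records for one trait and lactation: one row per animal with
#'   the trait column, class-variable columns, covariate columns, and
#'   optionally the tested factor column. Rows with missing values in any
#'   used column are dropped.
#' @param trait Name of the response column.
#' @param ainv Sparse A-inverse from [build_A_inverse()] (its dimnames define
#'   the animal order); every record's `animal` must appear in it.
#' @param factor_name Optional name of the tested factor column.
#' @param class_vars Fixed-effect class variables (default `"hys"`).
#' @param covariates Covariate columns (default `"calving_age"`).
#' @param lambda_range Search range for `lambda` (default `c(1e-3, 1e3)`,
#'   i.e. heritability between ~0.001 and ~0.999).
#' @param tol Convergence tolerance on `log(lambda)` (default 1e-6).
#' @return A `lactsnp_animal_model` object with variance components, fixed
#'   effect solutions and covariance, BLUPs, and bookkeeping for
#'   [ls_means()] and [test_factor()].
#' @export
fit_animal_model <- function(data, trait, ainv, factor_name = NULL,
                             class_vars = "hys", covariates = "calving_age",
                             lambda_range = c(1e-3, 1e3), tol = 1e-6) {
  used <- c("animal", trait, class_vars, covariates, factor_name)
  miss <- setdiff(used, names(data))
  if (length(miss)) abort(paste0("data lacks column(s): ", paste(miss, collapse = ", ")))
  df <- as.data.frame(data[, used])
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) abort("no complete records to fit")
  for (v in c(class_vars, factor_name)) {
    fv <- factor(df[[v]])
    if (any(table(fv) == 0)) {
      warn(paste0("dropping empty level(s) of ", v))
      fv <- droplevels(fv)
    }
    df[[v]] <- fv
  }
  # factors with a single observed level carry no contrast and leave the model
  term_labels <- c(class_vars, covariates, factor_name)
  single <- vapply(term_labels, function(v) is.factor(df[[v]]) && nlevels(df[[v]]) < 2, TRUE)
  term_labels <- term_labels[!single]
  if (!length(term_labels)) term_labels <- "1"
  fml <- stats::as.formula(paste("~", paste(term_labels, collapse = " + ")))
  X <- model.matrix(fml, df)
  asn <- attr(X, "assign")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    abort(paste0("fixed-effect design is singular; confounded term(s): ",
                 paste(aliased, collapse = ", ")))
  }
  y <- df[[trait]]
  n <- length(y)
  p <- ncol(X)

  anim <- rownames(ainv)
  ai <- match(df$animal, anim)
  if (anyNA(ai)) {
    abort(paste0("animal absent from pedigree: ", df$animal[which(is.na(ai))[1]]))
  }
  q <- length(anim)
  Z <- sparseMatrix(i = seq_len(n), j = ai, x = 1, dims = c(n, q))
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  XtX <- crossprod(Xs); XtZ <- crossprod(Xs, Z); ZtZ <- crossprod(Z)
  Wty <- c(as.vector(crossprod(Xs, y)), as.vector(crossprod(Z, y)))
  yty <- sum(y^2)
  C0 <- rbind(cbind(XtX, XtZ), cbind(Matrix::t(XtZ), ZtZ))
  B <- Matrix::bdiag(Matrix::Matrix(0, p, p), ainv)
  C0 <- methods::as(C0, "CsparseMatrix")
  B <- methods::as(B, "CsparseMatrix")

  mme_solve <- function(lambda) {
    C <- Matrix::forceSymmetric(C0 + lambda * B)
    ch <- tryCatch(Cholesky(C, LDL = FALSE, perm = TRUE),
                   error = function(e) abort(paste0(
                     "mixed-model equations not positive definite (confounded terms?): ",
                     conditionMessage(e))))
    theta <- as.vector(Matrix::solve(ch, Wty, system = "A"))
    logdet <- 2 * Matrix::determinant(ch, sqrt = TRUE)$modulus[1]
    rss <- yty - sum(theta * Wty)
    sigma_e2 <- rss / (n - p)
    list(theta = theta, logdet = logdet, sigma_e2 = sigma_e2, chol = ch)
  }
  # -2 * restricted log-likelihood, up to an additive constant
  prof <- function(loglambda) {
    lambda <- exp(loglambda)
    s <- mme_solve(lambda)
    (n - p) * log(s$sigma_e2) - q * loglambda + s$logdet
  }
  opt <- optimize(prof, interval = log(lambda_range), tol = tol)
  lambda <- exp(opt$minimum)
  boundary <- opt$minimum < log(lambda_range[1]) + 1e-3 ||
    opt$minimum > log(lambda_range[2]) - 1e-3
  if (boundary) {
    warn("variance-ratio estimate at the search bound (heritability near 0 or 1)")
  }
  fit <- mme_solve(lambda)
  sigma_e2 <- fit$sigma_e2
  sigma_a2 <- sigma_e2 / lambda
  beta <- setNames(fit$theta[seq_len(p)], colnames(X))
  u <- setNames(fit$theta[p + seq_len(q)], anim)
  # Cov(beta_hat) = sigma_e2 * top-left block of C^{-1}
  E <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1, dims = c(p + q, p))
  Cinv_p <- Matrix::solve(Matrix::forceSymmetric(C0 + lambda * B), E)
  cov_beta <- sigma_e2 * as.matrix(Cinv_p[seq_len(p), , drop = FALSE])
  dimnames(cov_beta) <- list(colnames(X), colnames(X))

  xlevels <- lapply(df[, c(class_vars, factor_name), drop = FALSE], levels)
  cov_means <- vapply(covariates, function(v) mean(df[[v]]), 0)
  counts <- if (!is.null(factor_name)) table(df[[factor_name]]) else NULL
  structure(list(trait = trait, factor_name = factor_name,
                 class_vars = class_vars, covariates = covariates,
                 sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, lambda = lambda,
                 heritability = sigma_a2 / (sigma_a2 + sigma_e2),
                 minus2_reml = opt$objective,
                 beta = beta, cov_beta = cov_beta, u = u,
                 assign = asn, term_labels = term_labels,
                 xlevels = xlevels, cov_means = cov_means,
                 factor_counts = counts,
                 n = n, p = p, q = q, boundary = boundary),
            class = "lactsnp_animal_model")
}

#' @export
print.lactsnp_animal_model <- function(x, ...) {
  cat("Animal model fit:", x$trait, "(", x$n, "records,", x$q, "pedigree animals )\n")
  cat(sprintf("  sigma_a2 = %.4g  sigma_e2 = %.4g  h2 = %.3f\n",
              x$sigma_a2, x$sigma_e2, x$heritability))
  if (!is.null(x$factor_name)) cat("  tested factor:", x$factor_name, "\n")
  invisible(x)
}

# design-matrix columns belonging to one term label
term_columns <- function(fit, label) {
  ti <- match(label, fit$term_labels)
  which(fit$assign == ti)
}

#' Wald chi-square test of a fixed factor
#'
#' Tests the joint nullity of the factor's contrasts using the fixed-effect
#' covariance from the mixed-model equations; `df = #levels - 1`.
#'
#' @param fit A `lactsnp_animal_model`.
#' @param factor_name Factor to test (default: the fit's tested factor).
#' @return One-row tibble: `chisq`, `df`, `p_value`.
#' @export
test_factor <- function(fit, factor_name = fit$factor_name) {
  if (is.null(factor_name)) abort("no factor to test in this fit")
  idx <- term_columns(fit, factor_name)
  if (!length(idx)) {
    return(tibble(chisq = 0, df = 0L, p_value = 1))
  }
  b <- fit$beta[idx]
  V <- fit$cov_beta[idx, idx, drop = FALSE]
  w <- as.numeric(crossprod(b, solve(V, b)))
  df <- length(idx)
  tibble(chisq = w, df = as.integer(df),
         p_value = pchisq(w, df = df, lower.tail = FALSE))
}

#' Least-squares means of a factor
#'
#' Model-adjusted level means at balanced class-variable weights and the
#' grand covariate mean: `mu + level effect + average HYS + b * mean(M)`.
#' Standard errors come from the fixed-effect covariance.
#'
#' @inheritParams test_factor
#' @return Tibble `level`, `n`, `estimate`, `se`; the full covariance matrix
#'   of the level means is attached as attribute `"cov"`.
#' @export
ls_means <- function(fit, factor_name = fit$factor_name) {
  if (is.null(factor_name)) abort("fit has no factor")
  levs <- fit$xlevels[[factor_name]]
  p <- length(fit$beta)
  Lrow <- function(level) {
    l <- numeric(p)
    l[1] <- 1  # intercept
    for (cv in fit$class_vars) {
      idx <- term_columns(fit, cv)
      nl <- length(fit$xlevels[[cv]])
      l[idx] <- 1 / nl
    }
    for (v in fit$covariates) {
      ti <- match(v, fit$term_labels)
      l[which(fit$assign == ti)] <- fit$cov_means[v]
    }
    idx <- term_columns(fit, factor_name)
    if (length(idx)) {
      # treatment contrasts: baseline level has no column
      hit <- match(paste0(factor_name, level), names(fit$beta)[idx])
      if (!is.na(hit)) l[idx[hit]] <- 1
    }
    l
  }
  L <- do.call(rbind, lapply(levs, Lrow))
  est <- as.vector(L %*% fit$beta)
  V <- L %*% fit$cov_beta %*% Matrix::t(L)
  V <- as.matrix(V)
  cnt <- fit$factor_counts
  out <- tibble(level = levs,
                n = if (!is.null(cnt)) as.integer(cnt[levs]) else NA_integer_,
                estimate = est, se = sqrt(pmax(diag(V), 0)))
  attr(out, "cov") <- V
  out
}

#' Compact significance letters from pairwise comparisons
#'
#' Performs all pairwise Wald z-tests between factor level means and encodes
#' the result as compact letter displays by the insert-and-absorb algorithm:
#' levels sharing no lowercase letter differ at `p < 0.05`, no uppercase
#' letter at `p < 0.01`.
#'
#' @param means Tibble from [ls_means()] (with its `"cov"` attribute).
#' @param alpha1,alpha2 The two significance thresholds (0.05, 0.01).
#' @return Tibble `level`, `letters_05`, `letters_01` plus the matrix of
#'   pairwise p-values as attribute `"pairwise_p"`.
#' @export
pairwise_letters <- function(means, alpha1 = 0.05, alpha2 = 0.01) {
  V <- attr(means, "cov")
  k <- nrow(means)
  pm <- matrix(NA_real_, k, k, dimnames = list(means$level, means$level))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { pm[i, j] <- 1; next }
    vd <- V[i, i] + V[j, j] - 2 * V[i, j]
    z <- (means$estimate[i] - means$estimate[j]) / sqrt(max(vd, .Machine$double.eps))
    pm[i, j] <- 2 * stats::pnorm(-abs(z))
  }
  lower <- cld_letters(pm < alpha1, letters)
  upper <- cld_letters(pm < alpha2, LETTERS)
  out <- means |>
    select("level") |>
    mutate(letters_05 = lower, letters_01 = upper)
  attr(out, "pairwise_p") <- pm
  out
}

# insert-and-absorb compact letter display; sig is a logical k x k matrix
cld_letters <- function(sig, alphabet) {
  k <- nrow(sig)
  cols <- list(rep(TRUE, k))  # letter columns: membership vectors
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (!isTRUE(sig[i, j])) next
    for (ci in seq_along(cols)) {
      if (cols[[ci]][i] && cols[[ci]][j]) {
        new1 <- cols[[ci]]; new1[i] <- FALSE
        new2 <- cols[[ci]]; new2[j] <- FALSE
        cols[[ci]] <- new1
        cols[[length(cols) + 1]] <- new2
      }
    }
    # absorb: drop columns whose membership is a subset of another's
    drop <- rep(FALSE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && !drop[a] && !drop[b] && all(cols[[a]] <= cols[[b]]) &&
          any(cols[[a]] != cols[[b]])) drop[a] <- TRUE
    }
    # exact duplicates: keep the first
    if (!all(drop)) {
      keys <- vapply(cols, function(x) paste(as.integer(x), collapse = ""), "")
      drop <- drop | duplicated(keys)
    }
    cols <- cols[!drop]
  }
  # letter columns ordered by their first member so level 1 starts at "a"
  cols <- cols[order(vapply(cols, function(x) which(x)[1], 0))]
  memb <- do.call(cbind, cols)
  vapply(seq_len(k), function(i) {
    paste(alphabet[which(memb[i, ])], collapse = "")
  }, "")
}

#' Bonferroni correction
#'
#' Multiplies a raw p-value by the number of tests in its family, uncapped
#' (values above 1 are reported as such, mirroring published candidate-gene
#' tables).
#'
#' @param p Raw p-value(s).
#' @param m Family size (tests per gene for single-SNP scans, number of
#'   blocks for haplotype scans).
#' @return `p * m`.
#' @export
bonferroni <- function(p, m) {
  if (any(m < 1)) abort("Bonferroni family size must be >= 1")
  p * m
}

#' @export
tidy.lactsnp_animal_model <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta),
         std.error = sqrt(diag(x$cov_beta)))
}

#' @export
glance.lactsnp_animal_model <- function(x, ...) {
  tibble(sigma_a2 = x$sigma_a2, sigma_e2 = x$sigma_e2,
         heritability = x$heritability, lambda = x$lambda,
         minus2_reml = x$minus2_reml, nobs = x$n, n_fixed = x$p,
         n_animals = x$q, boundary = x$boundary)
}
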