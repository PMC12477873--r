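#' Filter metabolites by microbiome influence
#'
#' Keeps metabolites whose predicted flux is microbiome-influenced in
#' strictly more than `min_influenced_fraction` of samples; a metabolite
#' not influenced in 95% of samples or more (i.e. influenced in at most
#' 5%) is removed.
#'
#' @param influenced Samples x metabolites logical matrix of influence
#'   flags (NA cells ignored).
#' @param min_influenced_fraction Minimal influenced fraction (default
#'   0.05, strict).
#' @return Character vector of retained metabolite IDs.
#' @export
filter_metabolites_by_influence <- function(influenced,
                                            min_influenced_fraction = 0.05) {
  frac <- colMeans(influenced, na.rm = TRUE)
  colnames(influenced)[!is.na(frac) & frac > min_influenced_fraction]
}

# alternating least squares PCA with missing-value support
pca_als <- function(X, ncomp = 3, maxit = 200, tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, n - 1L, p)
  obs <- !is.na(X)
  X0 <- X
  X0[!obs] <- 0
  sv <- svd(X0, nu = ncomp, nv = ncomp)
  Tm <- sv$u %*% diag(sv$d[seq_len(ncomp)], ncomp)
  P <- sv$v
  if (!all(obs)) {
    last <- Inf
    for (it in seq_len(maxit)) {
      for (i in seq_len(n)) { # scores row-wise on observed cells
        o <- obs[i, ]
        Po <- P[o, , drop = FALSE]
        Tm[i, ] <- qr.coef(qr(Po), X[i, o])
      }
      Tm[is.na(Tm)] <- 0
      for (j in seq_len(p)) {
        o <- obs[, j]
        To <- Tm[o, , drop = FALSE]
        P[j, ] <- qr.coef(qr(To), X[o, j])
      }
      P[is.na(P)] <- 0
      fit <- tcrossprod(Tm, P)
      err <- sqrt(mean((X[obs] - fit[obs])^2))
      if (abs(last - err) < tol) break
      last <- err
    }
    # orthonormalize loadings, rotate scores accordingly
    qrP <- qr(P)
    P <- qr.Q(qrP)
    Tm <- Tm %*% t(qr.R(qrP))
    sv2 <- svd(Tm)
    Tm <- sv2$u %*% diag(sv2$d, length(sv2$d))
    P <- P %*% sv2$v
  }
  evar <- apply(Tm, 2, function(t) sum(t^2))
  total <- sum(X[obs]^2)
  list(scores = Tm, loadings = P,
       explained = if (total > 0) evar / total else rep(0, ncomp))
}

#' Outlier scoring by robust PCA on z-transformed fluxes
#'
#' Fits a PCA by alternating least squares (tolerating missing cells) on
#' column-z-scored fluxes, scores each sample by the Euclidean norm of its
#' principal-component scores weighted by the explained-variance fraction
#' of each component, and flags samples whose score exceeds
#' `Q3 + k_iqr * IQR`.
#'
#' @param flux_matrix Samples x metabolites numeric matrix (>= 3 samples,
#'   >= 2 metabolites).
#' @param k_iqr IQR multiplier for the flag threshold (default 3).
#' @param ncomp Number of components (default 3).
#' @return List with `scores` (named numeric) and `flagged` (character
#'   vector of sample IDs).
#' @export
detect_outliers <- function(flux_matrix, k_iqr = 3, ncomp = 3) {
  stopifnot(nrow(flux_matrix) >= 3, ncol(flux_matrix) >= 2)
  Z <- apply(flux_matrix, 2, function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x, na.rm = TRUE)) / s
  })
  rownames(Z) <- rownames(flux_matrix)
  if (all(Z == 0, na.rm = TRUE)) {
    warning("degenerate (constant) flux matrix: no outliers scored", call. = FALSE)
    sc <- stats::setNames(rep(0, nrow(Z)), rownames(Z))
    return(list(scores = sc, flagged = character(0)))
  }
  fit <- pca_als(Z, ncomp = ncomp)
  w <- fit$explained
  sc <- sqrt(rowSums(sweep(fit$scores, 2, w, "*")^2))
  names(sc) <- rownames(flux_matrix)
  q <- stats::quantile(sc, c(0.25, 0.75), names = FALSE)
  thr <- q[2] + k_iqr * (q[2] - q[1])
  list(scores = sc, flagged = names(sc)[sc > thr])
}

#' Log2 + z transformation of predicted fluxes
#'
#' Fluxes are log2 transformed and z-scored. When zeros are present, a
#' pseudocount of half the smallest positive value is added before the
#' log; the pseudocount used is recorded as an attribute.
#'
#' @param flux_vector Nonnegative numeric vector (NAs allowed, preserved).
#' @return Z-scored log2 fluxes with attribute `epsilon` (0 when no zeros).
#' @export
transform_fluxes <- function(flux_vector) {
  x <- flux_vector
  ok <- !is.na(x)
  if (!any(ok) || all(x[ok] == 0)) stopf("all fluxes are zero or missing")
  if (any(x[ok] < 0)) stopf("negative fluxes cannot be log-transformed")
  eps <- 0
  if (any(x[ok] == 0)) {
    eps <- min(x[ok][x[ok] > 0]) / 2
  }
  lx <- log2(x + eps)
  z <- (lx - mean(lx, na.rm = TRUE)) / stats::sd(lx, na.rm = TRUE)
  attr(z, "epsilon") <- eps
  z
}

#' Logistic regression of diagnosis on a predicted flux
#'
#' Fits a maximum-likelihood logistic regression of case status on the
#' (transformed) flux, adjusting for the standard covariate set: age
#' (z-scored), sex, the six binary lifestyle/medication covariates, and
#' log10 total read count (z-scored). Covariates absent from `metadata`
#' are silently omitted, so small toy designs remain fittable. An optional
#' flux-by-sex or flux-by-age interaction term can be added; its Wald p is
#' then reported alongside.
#'
#' @param flux Numeric vector of transformed fluxes, aligned with
#'   `metadata` rows (NAs dropped listwise).
#' @param metadata Data frame with at least a `diagnosis` column
#'   (case level `"PD"`).
#' @param interaction `"none"`, `"sex"` or `"age"`.
#' @return One-row data frame (two rows with an interaction): `term`,
#'   `beta`, `ci_lo`, `ci_hi`, `p`, `n`, `separation`.
#' @export
flux_logistic_regression <- function(flux, metadata,
                                     interaction = c("none", "sex", "age")) {
  interaction <- match.arg(interaction)
  stopifnot(length(flux) == nrow(metadata), "diagnosis" %in% names(metadata))
  df <- data.frame(status = as.integer(metadata$diagnosis == "PD"), flux = flux)
  covs <- character(0)
  if ("age" %in% names(metadata)) {
    df$age_z <- as.numeric(scale(metadata$age)); covs <- c(covs, "age_z")
  }
  if ("sex" %in% names(metadata)) {
    df$sex <- factor(metadata$sex); covs <- c(covs, "sex")
  }
  for (v in c("alcohol", "laxatives", "antihistamines", "mood_meds",
              "pain_meds", "sleep_aid")) {
    if (v %in% names(metadata)) { df[[v]] <- metadata[[v]]; covs <- c(covs, v) }
  }
  if ("read_count" %in% names(metadata)) {
    df$log_reads_z <- as.numeric(scale(log10(metadata$read_count)))
    covs <- c(covs, "log_reads_z")
  }
  rhs <- c("flux", covs)
  if (interaction == "sex") rhs <- c(rhs, "flux:sex")
  if (interaction == "age") rhs <- c(rhs, "flux:age_z")
  fml <- stats::as.formula(paste("status ~", paste(rhs, collapse = " + ")))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  separation <- !fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  pull <- function(term_pattern, label) {
    row <- grep(term_pattern, rownames(sm))
    if (length(row) != 1L) return(NULL)
    est <- sm[row, 1]; se <- sm[row, 2]
    data.frame(term = label,
               beta = if (separation) NA_real_ else est,
               ci_lo = if (separation) NA_real_ else est - stats::qnorm(0.975) * se,
               ci_hi = if (separation) NA_real_ else est + stats::qnorm(0.975) * se,
               p = sm[row, 4], n = nrow(df), separation = separation,
               stringsAsFactors = FALSE)
  }
  out <- pull("^flux$", "flux")
  if (interaction != "none") {
    out <- rbind(out, pull("^flux:", paste0("flux:", interaction)))
  }
  out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NAs preserved).
#' @return Step-up BH adjusted values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Fisher's exact test on a 2x2 case-control table
#'
#' Reports the sample odds ratio `(pd_yes * ctrl_no) / (pd_no * ctrl_yes)`
#' (with a 0.5 continuity correction and a note when a cell is zero), the
#' two-sided Fisher exact p, and a Wald 95% CI on the log odds ratio.
#'
#' @param pd_yes,pd_no,ctrl_yes,ctrl_no Nonnegative integer cell counts.
#' @return List with `or`, `p`, `ci` (length-2), `continuity_corrected`.
#' @export
fisher_2x2 <- function(pd_yes, pd_no, ctrl_yes, ctrl_no) {
  cells <- c(pd_yes, pd_no, ctrl_yes, ctrl_no)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  tab <- matrix(cells, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stopf("every margin of the 2x2 table must be positive")
  }
  p <- stats::fisher.test(tab)$p.value
  cc <- any(cells == 0)
  if (cc) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  list(or = or, p = p, ci = ci, continuity_corrected = cc)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when both groups have at most 10 observations and no
#' ties; mid-rank normal approximation otherwise.
#'
#' @param x,y Non-empty numeric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxon_ranksum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= 10 && length(y) <= 10 && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact)$p.value)
}

#' Cohort summary in case-control table form
#'
#' Fisher sample odds ratios and exact p for binary covariates, Wilcoxon
#' rank-sum p for numeric ones, case vs control.
#'
#' @param metadata Metadata data frame (see
#'   [generate_abundance_cohort()]).
#' @return Data frame, one row per covariate.
#' @export
cohort_summary <- function(metadata) {
  pd <- metadata$diagnosis == "PD"
  rows <- list()
  bin_vars <- intersect(c("alcohol", "laxatives", "pain_meds", "mood_meds",
                          "antihistamines", "sleep_aid"), names(metadata))
  if ("sex" %in% names(metadata)) {
    m <- as.integer(metadata$sex == "male")
    ft <- fisher_2x2(sum(m[pd]), sum(!m[pd]), sum(m[!pd]), sum(!m[!pd]))
    rows[["sex_male"]] <- data.frame(variable = "sex_male", type = "binary",
                                     or = ft$or, ci_lo = ft$ci[1], ci_hi = ft$ci[2],
                                     p = ft$p, stringsAsFactors = FALSE)
  }
  for (v in bin_vars) {
    b <- metadata[[v]]
    ft <- fisher_2x2(sum(b[pd]), sum(1 - b[pd]), sum(b[!pd]), sum(1 - b[!pd]))
    rows[[v]] <- data.frame(variable = v, type = "binary", or = ft$or,
                            ci_lo = ft$ci[1], ci_hi = ft$ci[2], p = ft$p,
                            stringsAsFactors = FALSE)
  }
  for (v in intersect(c("age", "bmi", "read_count"), names(metadata))) {
    rows[[v]] <- data.frame(variable = v, type = "numeric", or = NA_real_,
                            ci_lo = NA_real_, ci_hi = NA_real_,
                            p = wilcoxon_ranksum(metadata[[v]][pd],
                                                 metadata[[v]][!pd]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
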