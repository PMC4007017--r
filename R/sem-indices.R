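#' Goodness-of-fit index battery
#'
#' `gfi()` is the maximum-likelihood goodness-of-fit index
#' `1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2]`; `cfi()` the
#' comparative fit index against an independence baseline,
#' `1 - max(chisq_m - df_m, 0) / max(chisq_b - df_b, chisq_m - df_m, 0)`
#' (1 when the denominator vanishes); `rmsea()` the root-mean-square
#' error of approximation
#' `sqrt(max(chisq - df, 0) / (df * (N - 1)))` (`NA` when df = 0).
#' The conventional acceptance battery requires GFI and CFI above 0.95
#' and RMSEA below 0.05, alongside a non-significant chi-square.
#'
#' @param S sample covariance.
#' @param Sigma fitted model-implied covariance.
#' @param chisq_m,df_m target-model chi-square statistic and df.
#' @param chisq_b,df_b baseline (independence) model chi-square and df.
#' @param chisq,df,N chi-square, its df, and the sample size.
#' @export
gfi <- function(S, Sigma) {
  W <- solve(Sigma, S)
  I <- diag(ncol(S))
  1 - sum(diag((W - I) %*% (W - I))) / sum(diag(W %*% W))
}

#' @rdname gfi
#' @export
cfi <- function(chisq_m, df_m, chisq_b, df_b) {
  num <- max(chisq_m - df_m, 0)
  den <- max(chisq_b - df_b, chisq_m - df_m, 0)
  if (den == 0) return(1)
  min(max(1 - num / den, 0), 1)
}

#' @rdname gfi
#' @export
rmsea <- function(chisq, df, N) {
  if (df == 0) return(NA_real_)
  sqrt(max(chisq - df, 0) / (df * (N - 1)))
}

#' Chi-square-based information criteria
#'
#' `AIC = chisq + 2 t` and `BIC = chisq + t log(N)` with `t` the free
#' parameter count. These omit the saturated-model log-likelihood
#' constant, so only differences between models fitted to the same
#' moments are meaningful (the convention used by common SEM software).
#'
#' @param chisq model chi-square.
#' @param t_free free-parameter count.
#' @param N sample size (>= 2).
#' @return named list with `AIC` and `BIC`.
#' @export
information_criteria <- function(chisq, t_free, N) {
  if (N < 2) stop_validation("N must be >= 2")
  list(AIC = chisq + 2 * t_free, BIC = chisq + t_free * log(N))
}

#' Does a fit meet the conventional acceptance battery?
#'
#' Non-significant chi-square (p > 0.05), GFI > 0.95, CFI > 0.95 and
#' RMSEA < 0.05.
#'
#' @param fit a [fit_ml()] result.
#' @param p_min,gfi_min,cfi_min,rmsea_max the four thresholds.
#' @export
meets_fit_criteria <- function(fit, p_min = 0.05, gfi_min = 0.95,
                               cfi_min = 0.95, rmsea_max = 0.05) {
  stopifnot(inherits(fit, "sem_fit"))
  ok_p <- is.na(fit$p_chi) || fit$p_chi > p_min
  ok_rmsea <- is.na(fit$RMSEA) || fit$RMSEA < rmsea_max
  isTRUE(ok_p && fit$GFI > gfi_min && fit$CFI > cfi_min && ok_rmsea)
}

#' Significance tiers of the fitted paths
#'
#' Maps each path's two-sided p-value onto the three display tiers used
#' for connectivity diagrams: `"p<0.001"`, `"p<0.01"`, and `"ns"`
#' (p >= 0.01; the boundary itself is non-significant).
#'
#' @param fit a converged [fit_ml()] result.
#' @return data.frame with columns `from`, `to`, `p_value`, `tier`.
#' @export
classify_path_tiers <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged) stop("refusing to tier paths of a non-converged fit")
  p <- fit$paths$p_value
  tier <- ifelse(p < 0.001, "p<0.001", ifelse(p < 0.01, "p<0.01", "ns"))
  data.frame(from = fit$paths$from, to = fit$paths$to,
             p_value = p, tier = tier)
}

#' Compare path-significance tiers across conditions
#'
#' Reports, per directed path present in any condition's model, the
#' tier in each condition, and flags paths that are strong (p < 0.001)
#' in at least one condition but non-significant (or absent) in
#' another. Raw coefficients are never compared across different
#' topologies; only the tier pattern is.
#'
#' @param fits named list of converged [fit_ml()] results sharing one
#'   variable set.
#' @return list with `tiers` (wide data.frame, one tier column per
#'   condition; absent paths are `"absent"`) and `flagged` (subset
#'   strong somewhere, ns/absent elsewhere).
#' @export
compare_groups <- function(fits) {
  if (length(fits) < 2 || is.null(names(fits)) || any(names(fits) == ""))
    stop_validation("fits must be a named list of two or more sem_fit objects")
  vars <- lapply(fits, function(f) sort(f$model$variables))
  if (!all(vapply(vars, identical, logical(1), vars[[1]])))
    stop_validation("all fits must share the same variable set")
  bad <- names(fits)[!vapply(fits, function(f) isTRUE(f$converged), logical(1))]
  if (length(bad))
    stop("cannot compare: non-converged fit(s): ", paste(bad, collapse = ", "))
  tier_tabs <- lapply(fits, classify_path_tiers)
  all_paths <- unique(do.call(rbind, lapply(tier_tabs, `[`, c("from", "to"))))
  rownames(all_paths) <- NULL
  out <- all_paths
  for (cond in names(fits)) {
    tt <- tier_tabs[[cond]]
    key <- paste(tt$from, tt$to)
    out[[cond]] <- tt$tier[match(paste(out$from, out$to), key)]
    out[[cond]][is.na(out[[cond]])] <- "absent"
  }
  tiers <- as.matrix(out[names(fits)])
  strong_somewhere <- apply(tiers == "p<0.001", 1, any)
  weak_somewhere <- apply(matrix(tiers %in% c("ns", "absent"),
                                 nrow(tiers)), 1, any)
  list(tiers = out, flagged = out[strong_somewhere & weak_somewhere, ,
                                  drop = FALSE])
}

#' Write a fit-statistic table (one row per condition) as TSV
#'
#' Columns: model, chisq, df, p, GFI, CFI, RMSEA, AIC, BIC.
#' @param fits named list of [fit_ml()] results.
#' @param path file path.
#' @return the table, invisibly written to `path` if given.
#' @export
fit_table <- function(fits, path = NULL) {
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm, chisq = f$chisq, df = f$df, p = f$p_chi,
               GFI = f$GFI, CFI = f$CFI, RMSEA = f$RMSEA,
               AIC = f$AIC, BIC = f$BIC)
  }))
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}

#' Write the per-path estimate table as TSV
#'
#' Columns: from, to, estimate, se, z, p, beta, tier.
#' @param fit a [fit_ml()] result.
#' @param path file path.
#' @export
path_table <- function(fit, path = NULL) {
  tab <- fit$paths
  names(tab)[names(tab) == "p_value"] <- "p"
  tab$tier <- classify_path_tiers(fit)$tier
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}
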