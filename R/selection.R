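#' Deviance Information Criterion of a fitted model
#'
#' Computes DIC from the pooled posterior draws: the deviance
#' `D(theta) = -2 log L(theta)` averaged over draws (`dbar`), the deviance
#' at the pointwise posterior mean of every parameter entering the linear
#' predictor and `sigma2` (`d_at_mean`), the effective number of parameters
#' `p_d = dbar - d_at_mean`, and `dic = dbar + p_d`. The deviance is
#' conditional (focused) on all sampled parameters, including the hour
#' effects and individual effects, matching the observed-data deviance a
#' Gibbs-sampler engine reports for this hierarchy; posterior means are
#' taken on each parameter's sampled scale (e.g. the mean of `sigma2`, not
#' of `1/sigma2`).
#'
#' @param fit a [diel_fit()].
#' @return object of class `dic_result` with fields `spec_id`, `dbar`,
#'   `d_at_mean`, `p_d`, `dic`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "diel_fit"))
  if (nrow(fit$draws) == 0L) stop("fit has no posterior draws")
  dev <- deviance_of_draws(fit, fit$draws)
  dbar <- mean(dev)
  d_at_mean <- deviance_of_draws(fit, matrix(colMeans(fit$draws), 1,
                                             ncol(fit$draws),
                                             dimnames = list(NULL, colnames(fit$draws))))
  p_d <- dbar - d_at_mean
  structure(list(spec_id = fit$spec$id, dbar = dbar, d_at_mean = d_at_mean,
                 p_d = p_d, dic = dbar + p_d),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("model %d: Dbar = %.1f, pD = %.1f, DIC = %.1f\n",
              x$spec_id, x$dbar, x$p_d, x$dic))
  invisible(x)
}

# Deviance of each draw row, through the compiled evaluator.
deviance_of_draws <- function(fit, draws) {
  md <- fit$model_data
  lay <- fit$layout
  spec <- fit$spec
  n <- length(md$y)
  if (n == 0L) stop("no observations: deviance undefined")
  lam_idx <- (md$strat - 1L) * 24L + md$hour
  omega_idx <- if (lay$K) lay$omega_at + md$animal else integer(n)
  fix_idx <- md$fixmap
  if (ncol(fix_idx)) {
    fix_idx <- fix_idx + (fix_idx > 0L) * lay$fixed_at
    storage.mode(fix_idx) <- "integer"
  }
  J <- length(spec$features)
  beta_idx <- phi_idx <- matrix(0L, n, J)
  off <- 0L
  for (jpos in seq_len(J)) {
    g <- md$agrp[, jpos]
    beta_idx[, jpos] <- lay$beta_at + off + g
    phi_idx[, jpos] <- lay$phi_at + off + g
    off <- off + md$ngrp[jpos]
  }
  deviance_draws_cpp(draws, md$y, as.integer(lam_idx), as.integer(omega_idx),
                     fix_idx, beta_idx, phi_idx, md$X,
                     as.integer(lay$sigma2_col))
}

#' Model-selection table
#'
#' Ranks fitted models by DIC: ascending DIC with `delta_dic` relative to
#' the best model, the rendered formula and the `K` column counting the
#' model's season-interacting terms (the season-indexed hour effect, the
#' sex-by-season interaction, and each season-indexed anthropogenic block).
#'
#' @param results list of `dic_result` objects (or a single one).
#' @return data frame `spec_id, formula, K, dbar, p_d, dic, delta_dic`,
#'   sorted by DIC.
#' @export
selection_table <- function(results) {
  if (inherits(results, "dic_result")) results <- list(results)
  if (!length(results)) stop("no DIC results supplied")
  df <- do.call(rbind, lapply(results, function(r) {
    spec <- model_spec(r$spec_id)
    data.frame(spec_id = r$spec_id, formula = render_formula(spec),
               K = interaction_count(spec),
               dbar = if (is.null(r$dbar)) NA_real_ else r$dbar,
               p_d = if (is.null(r$p_d)) NA_real_ else r$p_d,
               dic = r$dic, stringsAsFactors = FALSE)
  }))
  df <- df[order(df$dic, df$spec_id), ]
  df$delta_dic <- df$dic - min(df$dic)
  rownames(df) <- NULL
  df
}
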