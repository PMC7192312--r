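#' Construct a subjects x models log-evidence table
#'
#' @param log_evidence numeric matrix, subjects in rows, models in columns
#'   (nats); column names are model ids.
#' @param family_map optional named character vector mapping model id to
#'   family name.
#' @return an `evidence_table`.
#' @export
evidence_table <- function(log_evidence, family_map = NULL) {
  stopifnot(is.matrix(log_evidence), ncol(log_evidence) >= 2L,
            all(is.finite(log_evidence)))
  if (is.null(colnames(log_evidence)))
    colnames(log_evidence) <- paste0("m", seq_len(ncol(log_evidence)))
  if (!is.null(family_map))
    stopifnot(all(colnames(log_evidence) %in% names(family_map)))
  structure(list(log_evidence = log_evidence, family_map = family_map),
            class = "evidence_table")
}

#' Write / read an evidence table as CSV
#'
#' Plain subjects x models CSV with model ids as header.
#' @param ev an `evidence_table`.
#' @param path file path.
#' @return `read_evidence_csv` returns an `evidence_table`.
#' @export
write_evidence_csv <- function(ev, path) {
  stopifnot(inherits(ev, "evidence_table"))
  utils::write.csv(as.data.frame(ev$log_evidence), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_evidence_csv
#' @param family_map optional family map for the reloaded table.
#' @export
read_evidence_csv <- function(path, family_map = NULL) {
  evidence_table(as.matrix(utils::read.csv(path, check.names = FALSE)),
                 family_map)
}

# variational update of the Dirichlet posterior over model frequencies
# (random-effects BMS); returns the posterior alpha vector.
dirichlet_posterior <- function(lev, alpha0, max_iter = 500, tol = 1e-8) {
  K <- ncol(lev)
  alpha <- alpha0
  for (it in seq_len(max_iter)) {
    w <- sweep(lev, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- w - apply(w, 1, max)
    g <- exp(w) / rowSums(exp(w))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  alpha
}

# Monte Carlo exceedance: probability each column of the Dirichlet(alpha)
# sample is the largest; optionally aggregated over groups first.
mc_exceedance <- function(alpha, n_samples, seed, groups = NULL,
                          chunk = 1e5) {
  K <- length(alpha)
  set.seed(seed)
  n_groups <- if (is.null(groups)) K else max(groups)
  counts <- numeric(n_groups)
  done <- 0
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    r <- matrix(rgamma(m * K, shape = rep(alpha, each = m)), nrow = m)
    if (!is.null(groups)) {
      rg <- matrix(0, m, n_groups)
      for (k in seq_len(K)) rg[, groups[k]] <- rg[, groups[k]] + r[, k]
      r <- rg
    }
    win <- max.col(r, ties.method = "random")
    counts <- counts + tabulate(win, n_groups)
    done <- done + m
  }
  counts / n_samples
}

#' Random-effects Bayesian model selection
#'
#' Estimates the Dirichlet posterior over model frequencies in the population
#' from per-subject log model evidences (variational scheme, uniform
#' Dirichlet(1) prior by default), and computes each model's exceedance
#' probability - the probability that it is more frequent than every
#' competitor - by seeded Monte Carlo sampling of the posterior.
#'
#' Results are invariant to adding a per-subject constant to the evidences.
#'
#' @param ev an [evidence_table()].
#' @param n_samples Monte Carlo draws for the exceedance (default 1e6).
#' @param seed RNG seed for the exceedance sampling (default 1).
#' @param alpha0 prior Dirichlet weights (default 1 per model).
#' @return a `bms_result`: `dirichlet_alpha`, `expected_freq`, `exceedance`
#'   (each named by model), plus `n_samples` and `seed`.
#' @export
rfx_bms <- function(ev, n_samples = 1e6, seed = 1, alpha0 = NULL) {
  stopifnot(inherits(ev, "evidence_table"))
  lev <- ev$log_evidence
  K <- ncol(lev)
  if (is.null(alpha0)) alpha0 <- rep(1, K)
  stopifnot(length(alpha0) == K, all(alpha0 > 0))
  alpha <- dirichlet_posterior(lev, alpha0)
  xp <- mc_exceedance(alpha, n_samples, seed)
  structure(list(
    dirichlet_alpha = setNames(alpha, colnames(lev)),
    expected_freq = setNames(alpha / sum(alpha), colnames(lev)),
    exceedance = setNames(xp, colnames(lev)),
    n_samples = n_samples, seed = seed
  ), class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result>\n")
  print(round(rbind(expected_freq = x$expected_freq,
                    exceedance = x$exceedance), 4))
  invisible(x)
}

#' Family-level random-effects inference, then BMS within the winning family
#'
#' Groups models into families (e.g. linear- vs nonlinear-intrinsic), adjusts
#' the Dirichlet prior so every family carries equal prior mass regardless of
#' its size (prior weight 1/family-size per model), and computes family
#' exceedance probabilities by Monte Carlo aggregation of the model-frequency
#' posterior. Model-level BMS with a uniform prior is then run restricted to
#' the winning family.
#'
#' @param ev an [evidence_table()]; `families` defaults to its `family_map`.
#' @param families named character vector (model id -> family), partitioning
#'   the models.
#' @param n_samples,seed Monte Carlo settings as in [rfx_bms()].
#' @return a `family_bms`: `family_alpha` (summed per family),
#'   `family_expected_freq`, `family_exceedance`, `winning_family`, and
#'   `within` (the `bms_result` over the winning family's models).
#' @export
family_inference <- function(ev, families = NULL, n_samples = 1e6, seed = 1) {
  stopifnot(inherits(ev, "evidence_table"))
  families <- families %||% ev$family_map
  if (is.null(families)) stop("no family map supplied", call. = FALSE)
  lev <- ev$log_evidence
  ids <- colnames(lev)
  stopifnot(all(ids %in% names(families)))
  fam <- factor(families[ids])
  fam_names <- levels(fam)
  sizes <- table(fam)
  alpha0 <- 1 / as.numeric(sizes[fam])      # equal prior mass per family
  alpha <- dirichlet_posterior(lev, alpha0)
  fx <- mc_exceedance(alpha, n_samples, seed, groups = as.integer(fam))
  fam_alpha <- tapply(alpha, fam, sum)
  winner <- fam_names[which.max(fx)]
  sub <- ids[fam == winner]
  within <- if (length(sub) >= 2) {
    rfx_bms(evidence_table(lev[, sub, drop = FALSE]),
            n_samples = n_samples, seed = seed + 1)
  } else {
    # single-model family: within-family comparison is trivial
    structure(list(dirichlet_alpha = setNames(NA_real_, sub),
                   expected_freq = setNames(1, sub),
                   exceedance = setNames(1, sub),
                   n_samples = 0, seed = seed + 1), class = "bms_result")
  }
  structure(list(
    family_alpha = fam_alpha,
    family_expected_freq = fam_alpha / sum(fam_alpha),
    family_exceedance = setNames(fx, fam_names),
    winning_family = winner,
    within = within,
    n_samples = n_samples, seed = seed
  ), class = "family_bms")
}

#' @export
print.family_bms <- function(x, ...) {
  cat(sprintf("<family_bms> winner: %s\n", x$winning_family))
  print(round(rbind(expected_freq = as.numeric(x$family_expected_freq),
                    exceedance = as.numeric(x$family_exceedance)), 4))
  invisible(x)
}
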