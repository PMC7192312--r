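#' Gamma-shaped extrinsic input
#'
#' The network input is a gamma-density bump whose mode sits `peak_ms` before
#' EMG onset (default -400 ms, capturing the peak of the readiness potential
#' in self-initiated movement) with a standard deviation of `dispersion_ms`
#' (default 400 ms). Shape k and scale are solved from the mode offset m and
#' SD s via (k-1)*scale = m and sqrt(k)*scale = s, and the bump is
#' peak-normalized to 1. On the default [-1000, 0] ms analysis grid this
#' gives shape 4 and scale 200 ms exactly.
#'
#' @param times time grid in ms (0 = EMG onset); must start before `peak_ms`.
#' @param peak_ms mode of the bump, ms relative to EMG onset (default -400).
#' @param dispersion_ms SD of the (un-truncated) gamma density in ms
#'   (default 400).
#' @return numeric vector u(t), non-negative, max 1 at the mode.
#' @export
gamma_input <- function(times, peak_ms = -400, dispersion_ms = 400) {
  stopifnot(length(times) > 1, dispersion_ms > 0)
  m <- peak_ms - times[1]
  if (m <= 0)
    stop("analysis window must start before the input peak", call. = FALSE)
  s2 <- dispersion_ms^2
  # s2*k^2 - (2*s2 + m^2)*k + s2 = 0, take the root with k > 1
  b <- 2 * s2 + m^2
  k <- (b + sqrt(b^2 - 4 * s2^2)) / (2 * s2)
  scale <- m / (k - 1)
  u <- dgamma(times - times[1], shape = k, scale = scale)
  u / dgamma(m, shape = k, scale = scale)
}

#' Construct a single DCM-IR model
#'
#' A model is the network plus a per-connection coupling rule. Each ordered
#' region pair carries a flag: "absent" (no coupling), "linear"
#' (within-mode only: the M x M block is diagonal) or "nonlinear"
#' (full M x M block, allowing cross-frequency influence). Intrinsic
#' (within-region, diagonal) blocks are always present; whether they are
#' linear or nonlinear is the family flag.
#'
#' @param network a [network_spec()].
#' @param M number of spectral modes (default 4).
#' @param extrinsic J x J character matrix of flags ("absent", "linear",
#'   "nonlinear"); entry \[i, j\] is the connection from region j to region i.
#'   The diagonal is ignored. Default: all extrinsic connections "nonlinear".
#' @param intrinsic_nonlinear logical; `TRUE` gives full intrinsic blocks.
#' @param input list with `peak_ms` and `dispersion_ms` for [gamma_input()];
#'   input weights enter through the C vector on the input region's modes.
#' @param tau time constant in seconds (fixed scaling factor, default 1).
#' @param name optional model id.
#' @return a `dcm_model` with the boolean `A_mask` ((J*M) x (J*M)) and
#'   `C_mask` (J*M, input-region rows only).
#' @export
dcm_model <- function(network, M = 4, extrinsic = NULL,
                      intrinsic_nonlinear = FALSE,
                      input = list(peak_ms = -400, dispersion_ms = 400),
                      tau = 1, name = NULL) {
  stopifnot(inherits(network, "network_spec"), M >= 1, tau > 0)
  J <- network$J
  if (is.null(extrinsic)) {
    extrinsic <- matrix("nonlinear", J, J)
  }
  stopifnot(is.matrix(extrinsic), all(dim(extrinsic) == J),
            all(extrinsic %in% c("absent", "linear", "nonlinear")))
  dimnames(extrinsic) <- list(network$regions$name, network$regions$name)
  diag(extrinsic) <- if (intrinsic_nonlinear) "nonlinear" else "linear"
  n <- J * M
  A_mask <- matrix(FALSE, n, n)
  for (i in seq_len(J)) for (j in seq_len(J)) {
    ri <- (i - 1) * M + seq_len(M)
    rj <- (j - 1) * M + seq_len(M)
    A_mask[ri, rj] <- switch(extrinsic[i, j],
                             absent = matrix(FALSE, M, M),
                             linear = diag(M) > 0,
                             nonlinear = matrix(TRUE, M, M))
  }
  in_idx <- match(network$input_region, network$regions$name)
  C_mask <- rep(FALSE, n)
  C_mask[(in_idx - 1) * M + seq_len(M)] <- TRUE
  structure(list(network = network, M = M, extrinsic = extrinsic,
                 intrinsic_nonlinear = intrinsic_nonlinear,
                 A_mask = A_mask, C_mask = C_mask,
                 input = input, tau = tau,
                 name = name %||% "model"),
            class = "dcm_model")
}

#' @export
print.dcm_model <- function(x, ...) {
  n_conn <- sum(x$extrinsic[row(x$extrinsic) != col(x$extrinsic)] != "absent")
  cat(sprintf("<dcm_model> %s: %d regions x %d modes, %d extrinsic connections, %s intrinsic\n",
              x$name, x$network$J, x$M, n_conn,
              if (x$intrinsic_nonlinear) "nonlinear" else "linear"))
  invisible(x)
}

# the five reduced variants: connections dropped relative to the full model
reduced_variants <- function() list(
  m1 = c("cPM->iPM"),
  m2 = c("iPM->cPM"),
  m3 = c("cPM->cM1"),
  m4 = c("iPM->iM1"),
  m5 = c("cPM->iPM", "iPM->cPM")
)

#' Build the twelve-model space
#'
#' Two families of six models over the five-region motor network. Family
#' "linear_intrinsic" (models 1-6) allows linear and nonlinear extrinsic
#' coupling but only linear (within-mode) intrinsic coupling; family
#' "nonlinear_intrinsic" (models 7-12) additionally allows nonlinear
#' intrinsic coupling. Within each family, five models drop one or two
#' premotor-origin connections (to the other premotor area or to M1) and the
#' sixth is fully connected - so model 12 is the fully connected model of
#' the nonlinear-intrinsic family.
#'
#' @param network a [network_spec()]; must contain cM1, iM1, cPM, iPM, SMA
#'   for the default reduced-model list.
#' @param M modes (default 4).
#' @param drops optional list of character vectors ("src->tgt") defining the
#'   reduced variants (default [reduced_variants()]).
#' @param ... passed to [dcm_model()] (input, tau).
#' @return a `model_space`: list of 12 `dcm_model`s plus a `families` map.
#' @export
build_model_space <- function(network = default_network(), M = 4,
                              drops = reduced_variants(), ...) {
  stopifnot(inherits(network, "network_spec"))
  nm <- network$regions$name
  needed <- unique(unlist(lapply(drops, function(d)
    unlist(strsplit(d, "->", fixed = TRUE)))))
  if (!all(needed %in% nm))
    stop("network lacks regions named in the reduced-model list", call. = FALSE)
  J <- network$J
  base <- matrix("nonlinear", J, J, dimnames = list(nm, nm))
  variants <- c(drops, list(full = character(0)))
  models <- list()
  fam <- character(0)
  k <- 0
  for (nonlin in c(FALSE, TRUE)) {
    for (v in seq_along(variants)) {
      k <- k + 1
      ext <- base
      for (d in variants[[v]]) {
        st <- strsplit(d, "->", fixed = TRUE)[[1]]
        ext[st[2], st[1]] <- "absent"   # [target, source]
      }
      models[[k]] <- dcm_model(network, M = M, extrinsic = ext,
                               intrinsic_nonlinear = nonlin,
                               name = sprintf("m%02d", k), ...)
      fam[k] <- if (nonlin) "nonlinear_intrinsic" else "linear_intrinsic"
    }
  }
  names(models) <- vapply(models, `[[`, "", "name")
  structure(list(models = models,
                 families = stats::setNames(fam, names(models))),
            class = "model_space")
}

#' @export
print.model_space <- function(x, ...) {
  cat(sprintf("<model_space> %d models; families: %s\n", length(x$models),
              paste(sprintf("%s (%d)", unique(x$families),
                            table(x$families)[unique(x$families)]),
                    collapse = ", ")))
  invisible(x)
}

#' Serialize a model space to a structured config list (round-trippable)
#'
#' @param ms a `model_space`.
#' @return a plain list suitable for `yaml::write_yaml()`.
#' @export
model_space_to_config <- function(ms) {
  stopifnot(inherits(ms, "model_space"))
  net <- ms$models[[1]]$network
  list(
    regions = lapply(seq_len(net$J), function(i)
      list(name = net$regions$name[i], x = net$regions$x[i],
           y = net$regions$y[i], z = net$regions$z[i])),
    input_region = net$input_region,
    M = ms$models[[1]]$M,
    tau = ms$models[[1]]$tau,
    input = ms$models[[1]]$input,
    models = lapply(ms$models, function(m) {
      ext <- m$extrinsic
      off <- which(row(ext) != col(ext) & ext != "nonlinear", arr.ind = TRUE)
      list(name = m$name,
           intrinsic_nonlinear = m$intrinsic_nonlinear,
           non_default = if (nrow(off)) lapply(seq_len(nrow(off)), function(r)
             list(from = colnames(ext)[off[r, 2]],
                  to = rownames(ext)[off[r, 1]],
                  flag = ext[off[r, 1], off[r, 2]])) else list())
    }))
}

#' Rebuild a model space from its config list
#'
#' @param cfg a list as produced by [model_space_to_config()].
#' @return a `model_space`.
#' @export
model_space_from_config <- function(cfg) {
  regions <- do.call(rbind, lapply(cfg$regions, function(r)
    data.frame(name = r$name, x = r$x, y = r$y, z = r$z)))
  net <- network_spec(regions, cfg$input_region)
  nm <- regions$name
  models <- lapply(cfg$models, function(mc) {
    ext <- matrix("nonlinear", net$J, net$J, dimnames = list(nm, nm))
    for (nd in mc$non_default) ext[nd$to, nd$from] <- nd$flag
    dcm_model(net, M = cfg$M, extrinsic = ext,
              intrinsic_nonlinear = isTRUE(mc$intrinsic_nonlinear),
              input = cfg$input, tau = cfg$tau, name = mc$name)
  })
  names(models) <- vapply(models, `[[`, "", "name")
  fam <- vapply(models, function(m)
    if (m$intrinsic_nonlinear) "nonlinear_intrinsic" else "linear_intrinsic", "")
  structure(list(models = models, families = fam), class = "model_space")
}
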