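# Thermodynamic occupancy model and Euler integration of expression over
# differentiation time.

#' Per-TF thermodynamic and chromatin parameters
#'
#' Builds the per-TF parameter table: the statistical weight `alpha_btm` of
#' the TF-BTM (basal transcriptional machinery) interaction (activators
#' favour the BTM-bound state, repressors disfavour it), the association
#' constant `k_max` of the consensus site, the chromatin modification
#' capacity `rho` (activators open chromatin, repressors compact it) and the
#' Gaussian amplitude `sigma_chrom` over which a bound TF influences
#' chromatin.
#'
#' @param condition a `grn_condition`.
#' @param alpha_activator,alpha_inhibitor BTM interaction weights.
#' @param k_max consensus-site association constant (set to 0 to knock a TF
#'   out).
#' @param rho_activator,rho_inhibitor chromatin modification capacities.
#' @param sigma_chrom chromatin modification amplitude in base pairs.
#' @return data.frame with one row per TF: `tf_id`, `role`, `alpha_btm`,
#'   `k_max`, `rho`, `sigma_chrom`.
#' @export
tf_params <- function(condition, alpha_activator = 2.0,
                      alpha_inhibitor = 0.005, k_max = 1.0,
                      rho_activator = 1.0, rho_inhibitor = -3.0,
                      sigma_chrom = 25) {
  tfs <- tf_ids(condition)
  role <- ifelse(condition$genes$kind[tfs] == "inhibitor",
                 "inhibitor", "activator")
  data.frame(
    tf_id = tfs,
    role = role,
    alpha_btm = ifelse(role == "activator", alpha_activator, alpha_inhibitor),
    k_max = rep(k_max, length(tfs)),
    rho = ifelse(role == "activator", rho_activator, rho_inhibitor),
    sigma_chrom = rep(sigma_chrom, length(tfs)),
    stringsAsFactors = FALSE
  )
}

#' Dynamics parameters
#'
#' @param b first-order degradation rate of all gene products per time step.
#' @param basal_mode how a promoter with no bound TF behaves:
#'   `"exclude-empty"` (default) removes the empty configuration from the
#'   BTM-bound partition sum, so an unregulated promoter is silent;
#'   `"include-empty"` keeps it (an unregulated promoter transcribes at
#'   E = 0.5); `"btm-weight"` gives the empty configuration an explicit
#'   basal weight `q_btm`.
#' @param q_btm basal BTM weight (only used in `"btm-weight"` mode).
#' @param beta chromatin plasticity scaling factor.
#' @param delta constant per-step change in chromatin accessibility
#'   (negative: chromatin closes where no activator binds).
#' @param T number of Euler steps of size 1 between the initial and the
#'   adult expression pattern.
#' @param llr_scale how the bits-valued LLR deficit of a site enters its
#'   Boltzmann weight `exp(llr_scale * (llr - llr_max))`: 1 exponentiates
#'   the bits value with base e (the default), `log(2)` recomputes
#'   the LLR in natural-log units first.
#' @return a list of class `grn_dynamics_params`.
#' @export
dynamics_params <- function(b = 0.2,
                            basal_mode = c("exclude-empty", "include-empty",
                                           "btm-weight"),
                            q_btm = 0.001, beta = 0.8, delta = -0.2,
                            T = 10L, llr_scale = 1) {
  basal_mode <- match.arg(basal_mode)
  stopifnot(b > 0, b <= 1, T >= 1)
  structure(list(b = b, basal_mode = basal_mode, q_btm = q_btm,
                 beta = beta, delta = delta, T = as.integer(T),
                 llr_scale = llr_scale),
            class = "grn_dynamics_params")
}

basal_mode_code <- function(mode) {
  match(mode, c("exclude-empty", "include-empty", "btm-weight")) - 1L
}

#' Statistical weight of one bound binding site
#'
#' The Boltzmann factor a bound site contributes to a promoter
#' configuration: local chromatin accessibility times TF concentration
#' times the consensus association constant times `exp(llr - llr_max)`
#' (the LLR deficit of the site relative to the consensus, in bits,
#' exponentiated base e).
#'
#' @param site one row of a site data.frame (needs `q_base`), or a numeric
#'   `q_base` value.
#' @param tf_conc TF concentration (dimensionless).
#' @param k_max association constant of the consensus site.
#' @param accessibility chromatin accessibility at the site (1 without the
#'   chromatin layer).
#' @return the dimensionless weight `q`.
#' @export
#' @examples
#' site_weight(1.0, tf_conc = 1)        # consensus site: q = 1
#' site_weight(exp(-1), tf_conc = 1)    # one bit below consensus
site_weight <- function(site, tf_conc, k_max = 1.0, accessibility = 1.0) {
  q_base <- if (is.numeric(site)) site else site$q_base
  accessibility * tf_conc * k_max * q_base
}

#' Promoter activation: fractional BTM occupancy
#'
#' Computes the transcription rate `E = Z_ON / (Z_ON + Z_OFF)` of a
#' promoter from the statistical weights of its bound sites. With `n`
#' independent sites the `2^n`-configuration partition sums factorize:
#' `Z_OFF = prod(1 + q_i)` and the BTM-bound sum is
#' `prod(1 + q_i * alpha_i)`, from which the empty configuration's weight 1
#' is removed under the default `"exclude-empty"` mode. Computation is done
#' in log space so promoters with many sites cannot overflow.
#'
#' @param q numeric vector of site weights (see [site_weight()]).
#' @param alpha numeric vector of TF-BTM interaction weights per site.
#' @param basal_mode see [dynamics_params()].
#' @param q_btm basal BTM weight for `"btm-weight"` mode.
#' @return the activation E in `[0, 1)`.
#' @export
#' @examples
#' promoter_activation(1, 2)                      # one activator site: 0.5
#' promoter_activation(c(1, 1), c(2, 0.005))      # activator + repressor
promoter_activation <- function(q, alpha,
                                basal_mode = c("exclude-empty",
                                               "include-empty", "btm-weight"),
                                q_btm = 0.001) {
  basal_mode <- match.arg(basal_mode)
  stopifnot(length(q) == length(alpha), all(is.finite(q)), all(q >= 0))
  log_zoff <- sum(log1p(q))
  log_zon_full <- sum(log1p(q * alpha))
  log_zon <- switch(basal_mode,
    "exclude-empty" = {
      if (log_zon_full <= 0) return(0)
      if (log_zon_full < 30) log(expm1(log_zon_full)) else log_zon_full
    },
    "include-empty" = log_zon_full,
    "btm-weight" = log(q_btm) + log_zon_full
  )
  1 / (1 + exp(log_zoff - log_zon))
}

#' One Euler step of gene expression
#'
#' `x' = x + (E - b x)` with step size 1, clamped at 0 from below. At
#' sustained maximal activation `E = 1` the trajectory converges towards
#' the ceiling `(1 - (1-b)^T)/b` after `T` steps from 0.
#'
#' @param x current concentration(s).
#' @param E transcription rate(s) in `[0, 1)`.
#' @param b degradation rate.
#' @return updated concentration(s).
#' @export
step_expression <- function(x, E, b = 0.2) {
  pmax(0, x + (E - b * x))
}

#' One Euler step of chromatin accessibility along a promoter
#'
#' Each bound TF modifies chromatin around its site with strength
#' proportional to its concentration, the affinity of the site and its
#' chromatin modification capacity `rho`, spread as a Gaussian of width
#' `sigma_chrom` base pairs; the summed TF effect is normalized by the
#' total number of binding sites `H` on the promoter. Accessibility also
#' changes by a constant rate `delta` (negative: closing), scaled like the
#' TF term by the plasticity factor `beta`, and is clamped at 0.
#'
#' @param phi numeric vector of per-nucleotide accessibilities.
#' @param sites data.frame of all binding sites on this promoter
#'   (columns `tf_id`, `position`, `q_base`).
#' @param tf_conc named or TF-indexed numeric vector of TF concentrations.
#' @param tfp per-TF parameter table from [tf_params()].
#' @param beta,delta see [dynamics_params()].
#' @return the updated accessibility vector.
#' @export
step_chromatin <- function(phi, sites, tf_conc, tfp, beta = 0.8,
                           delta = -0.2) {
  P <- length(phi)
  H <- nrow(sites)
  contrib <- numeric(P)
  if (H > 0) {
    pos <- seq_len(P) - 1L
    for (s in seq_len(H)) {
      i <- match(sites$tf_id[s], tfp$tf_id)
      conc <- tf_conc[sites$tf_id[s]]
      if (conc == 0) next
      d2 <- (pos - sites$position[s])^2
      contrib <- contrib + conc * tfp$k_max[i] * tfp$rho[i] *
        sites$q_base[s] * exp(-d2 / (2 * tfp$sigma_chrom[i]^2))
    }
    contrib <- contrib / H
  }
  pmax(0, phi + beta * (contrib + delta * phi))
}

#' Run the differentiation dynamics of one genome
#'
#' Integrates gene expression (and, for chromatin-enabled conditions,
#' per-nucleotide accessibility) over developmental time with a synchronous
#' Euler scheme: all transcription rates are computed from the state at
#' time t, then every gene (and every nucleotide) advances together. The
#' final time slice is the adult expression pattern.
#'
#' @param genome a `grn_genome` with scanned sites (see [scan_genome()]).
#' @param condition a `grn_condition`.
#' @param dyn dynamics parameters from [dynamics_params()].
#' @param tfp per-TF parameters from [tf_params()].
#' @return an object of class `grn_expression`: list with `x` (genes x
#'   cells x T+1 trajectory array), `final` (genes x cells adult pattern),
#'   `E` (last-step transcription rates), and `phi` (positions x genes x
#'   cells accessibility, chromatin conditions only).
#' @export
run_differentiation <- function(genome, condition, dyn = dynamics_params(),
                                tfp = tf_params(condition)) {
  sites <- genome_sites(genome)
  G <- n_genes(condition)
  C <- condition$n_cells
  nTF <- length(tf_ids(condition))
  res <- cpp_run_dynamics(
    as.integer(sites$gene_id), as.integer(sites$tf_id),
    as.integer(sites$position), as.integer(sites$strand == "-"),
    as.numeric(sites$llr), site_qbase(sites, dyn),
    G, C, condition$promoter_length, nTF,
    condition$initial_pattern,
    tfp$alpha_btm, tfp$k_max, tfp$rho, tfp$sigma_chrom,
    dyn$b, dyn$T, basal_mode_code(dyn$basal_mode), dyn$q_btm,
    condition$chromatin_enabled, dyn$beta, dyn$delta)
  gene_names <- condition$genes$name
  cell_names <- colnames(condition$initial_pattern)
  dimnames(res$x) <- list(gene_names, cell_names, paste0("t", 0:dyn$T))
  final <- res$x[, , dyn$T + 1L, drop = FALSE]
  dim(final) <- c(G, C)
  dimnames(final) <- list(gene_names, cell_names)
  dimnames(res$E) <- list(gene_names, cell_names)
  out <- list(x = res$x, final = final, E = res$E)
  if (condition$chromatin_enabled) out$phi <- res$phi
  structure(out, class = "grn_expression")
}

# q_base rescaled if the dynamics ask for natural-log LLR units.
site_qbase <- function(sites, dyn) {
  if (dyn$llr_scale == 1) as.numeric(sites$q_base)
  else exp(log(sites$q_base) * dyn$llr_scale)
}

#' @export
print.grn_expression <- function(x, ...) {
  cat("grn_expression:", nrow(x$final), "genes x", ncol(x$final),
      "cells,", dim(x$x)[3] - 1L, "steps\n")
  cat("final pattern range:", format(range(x$final), digits = 4), "\n")
  invisible(x)
}
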