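# Cost-driven affine refinement: iterative re-matching of mutual nearest
# landmark pairs while a derivative-free simplex minimizes the mean squared
# matched-centroid distance over (tx, ty, theta, sx, sy).

#' Mutual-nearest-neighbour landmark pairing
#'
#' Moving landmarks are mapped through `transform`, then pairs are kept when
#' each point is the other's nearest neighbour and the distance is within
#' `gate_nm`.  The pairing is one-to-one by construction.
#'
#' @param ref,mov `centroid_set`s (or n x 2 matrices of nm positions).
#' @param transform optional `affine2d` applied to `mov` first.
#' @param gate_nm gating distance in nm (> 0).
#' @return a `matched_pairs` data.frame with columns `ref_index`,
#'   `mov_index`, `distance_nm` and a `gate_nm` attribute.
#' @export
match_pairs <- function(ref, mov, transform = NULL, gate_nm = 2000) {
  if (gate_nm <= 0)
    stop_clxm("clxm_input_error", "gate_nm must be positive")
  rp <- as_points(ref); mp <- as_points(mov)
  if (!is.null(transform)) mp <- apply_affine(transform, mp)
  empty <- data.frame(ref_index = integer(0), mov_index = integer(0),
                      distance_nm = numeric(0))
  if (nrow(rp) == 0 || nrow(mp) == 0)
    return(structure(empty, gate_nm = gate_nm, class = c("matched_pairs", "data.frame")))
  d <- sqrt(outer(rp[, 1], mp[, 1], "-")^2 + outer(rp[, 2], mp[, 2], "-")^2)
  nn_of_ref <- apply(d, 1, which.min)   # for each ref, nearest mov
  nn_of_mov <- apply(d, 2, which.min)   # for each mov, nearest ref
  ref_idx <- which(nn_of_mov[nn_of_ref] == seq_len(nrow(rp)))
  mov_idx <- nn_of_ref[ref_idx]
  dist <- d[cbind(ref_idx, mov_idx)]
  keep <- dist <= gate_nm
  structure(data.frame(ref_index = ref_idx[keep], mov_index = mov_idx[keep],
                       distance_nm = dist[keep]),
            gate_nm = gate_nm, class = c("matched_pairs", "data.frame"))
}

#' @noRd
refine_opts_default <- function() {
  list(gate_init_nm = 2000, gate_floor_nm = 300, gate_factor = 3,
       scale_bounds = c(0.8, 1.25), theta_bound_deg = 15,
       max_outer = 50L, optim_maxit = 500L, rel_tol = 1e-4,
       jitter_nm = 500)
}

#' @noRd
params_to_affine <- function(p, centre) {
  affine_transform(tx_nm = p[1], ty_nm = p[2], theta_deg = p[3],
                   sx = p[4], sy = p[5], centre_nm = centre)
}

#' @noRd
collinear_points <- function(pts, tol = 1e-6) {
  if (nrow(pts) < 3) return(TRUE)
  ctr <- scale(pts, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  sv[2] <= tol * max(sv[1], 1)
}

#' Cost-driven affine refinement of landmark correspondence
#'
#' ICP-style loop: under the current transform, moving landmarks are
#' re-matched to reference landmarks (mutual nearest neighbours within a
#' shrinking gate), then a Nelder-Mead simplex minimizes the mean squared
#' pair distance over translation, rotation and anisotropic scales.  The
#' rotation/scale pivot is the centroid of the reference landmark set.
#' Starts from the phase-correlation translation, choosing the best of a
#' 3 x 3 translation jitter grid around it.
#'
#' @param ref,mov `centroid_set`s (or n x 2 nm matrices).
#' @param init initial translation `(dx_nm, dy_nm)`, typically from
#'   [coarse_align_pcc()].
#' @param opts list overriding any of: `gate_init_nm` (2000), `gate_floor_nm`
#'   (300), `gate_factor` (3), `scale_bounds` (0.8..1.25), `theta_bound_deg`
#'   (15), `max_outer` (50), `optim_maxit` (500), `rel_tol` (1e-4),
#'   `jitter_nm` (500).
#' @return an `affine2d` (moving -> reference) with attributes `cost`
#'   (mean squared distance, nm^2), `rms_nm`, `n_pairs`, `outer_iters`,
#'   `trajectory` (per-iteration cost) and `converged`.
#' @export
refine_affine <- function(ref, mov, init = c(0, 0), opts = list()) {
  o <- utils::modifyList(refine_opts_default(), opts)
  rp <- as_points(ref); mp <- as_points(mov)
  if (nrow(rp) < 3 || nrow(mp) < 3 ||
      collinear_points(rp) || collinear_points(mp))
    stop_clxm("clxm_degenerate_geometry_error",
              "need at least 3 non-collinear landmarks on each side")
  centre <- colMeans(rp)

  pair_cost <- function(p, gate) {
    a <- params_to_affine(p, centre)
    prs <- match_pairs(rp, mp, a, gate)
    if (nrow(prs) < 3) return(Inf)
    mean(prs$distance_nm^2)
  }
  penalty <- function(p) {
    ex <- max(0, abs(p[3]) - o$theta_bound_deg) +
      max(0, o$scale_bounds[1] - p[4]) + max(0, p[4] - o$scale_bounds[2]) +
      max(0, o$scale_bounds[1] - p[5]) + max(0, p[5] - o$scale_bounds[2])
    1e8 * ex^2
  }

  # start: best of a 3x3 translation jitter grid around the PCC estimate
  starts <- expand.grid(jx = c(-1, 0, 1) * o$jitter_nm,
                        jy = c(-1, 0, 1) * o$jitter_nm)
  p <- c(init[1], init[2], 0, 1, 1)
  start_costs <- vapply(seq_len(nrow(starts)), function(i)
    pair_cost(c(init[1] + starts$jx[i], init[2] + starts$jy[i], 0, 1, 1),
              o$gate_init_nm), numeric(1))
  best <- which.min(start_costs)
  p[1] <- init[1] + starts$jx[best]; p[2] <- init[2] + starts$jy[best]

  gate <- o$gate_init_nm
  prev_cost <- Inf
  trajectory <- numeric(0)
  converged <- FALSE
  pairs_n <- 0L
  for (iter in seq_len(o$max_outer)) {
    prs <- match_pairs(rp, mp, params_to_affine(p, centre), gate)
    if (nrow(prs) < 3 ||
        collinear_points(rp[prs$ref_index, , drop = FALSE]))
      stop_clxm("clxm_degenerate_geometry_error",
                "fewer than 3 usable non-collinear pairs at iteration ", iter)
    pairs_n <- nrow(prs)
    fixed_cost <- function(pp) {
      q <- apply_affine(params_to_affine(pp, centre),
                        mp[prs$mov_index, , drop = FALSE])
      mean((q[, 1] - rp[prs$ref_index, 1])^2 +
           (q[, 2] - rp[prs$ref_index, 2])^2) + penalty(pp)
    }
    fit <- stats::optim(p, fixed_cost, method = "Nelder-Mead",
                        control = list(maxit = o$optim_maxit,
                                       parscale = c(100, 100, 0.5, 0.01, 0.01),
                                       reltol = 1e-10))
    p <- fit$par
    cost <- pair_cost(p, gate)
    trajectory <- c(trajectory, cost)
    gate <- max(o$gate_floor_nm, o$gate_factor * sqrt(cost))
    if (is.finite(prev_cost) &&
        abs(prev_cost - cost) <= o$rel_tol * max(prev_cost, 1e-12)) {
      converged <- TRUE
      break
    }
    prev_cost <- cost
  }
  a <- params_to_affine(p, centre)
  final_pairs <- match_pairs(rp, mp, a, gate)
  if (!converged && length(trajectory) >= o$max_outer) {
    cond <- structure(
      class = c("clxm_convergence_error", "clxm_error", "error", "condition"),
      list(message = sprintf(
        "affine refinement did not converge within %d iterations (best cost %.3g nm^2)",
        o$max_outer, min(trajectory)), call = sys.call(-1),
        best_so_far = a))
    stop(cond)
  }
  structure(a, cost = utils::tail(trajectory, 1),
            rms_nm = sqrt(utils::tail(trajectory, 1)),
            n_pairs = nrow(final_pairs), outer_iters = length(trajectory),
            trajectory = trajectory, converged = converged,
            gate_final_nm = gate, class = class(a))
}
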