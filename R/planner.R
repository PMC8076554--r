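#' Fixation policies and render contexts
#'
#' A policy is a candidate gaze: a labelled head pose plus egocentric eye
#' direction. A render context bundles everything the planner needs to turn
#' a policy and a room into a retinal observation: the retinal array, the
#' light, the interocular baseline, the blur width and an optional lesion.
#'
#' @param label policy label (used for deterministic tie-breaking).
#' @param place length-3 head position in meters.
#' @param head_dir length-2 `(heading, elevation)` in radians.
#' @param ego_dir length-2 egocentric eye direction in radians.
#' @param convergence convergence angle in radians.
#' @return `policy()` returns a `policy`; `render_context()` a
#'   `render_context`.
#' @export
policy <- function(label, place = c(0, 0, 1.5), head_dir = c(0, 0),
                   ego_dir = c(0, 0), convergence = 0) {
  structure(list(label = label,
                 pose = head_pose(place, head_dir),
                 eyes = eye_direction(ego_dir, convergence)),
            class = "policy")
}

#' @rdname policy
#' @param array a `retinal_array`.
#' @param light a `light_source`.
#' @param baseline interocular baseline in meters.
#' @param sigma_freq DCT blur width (default `min(dim)/6`).
#' @param lesion a `lesion_config`.
#' @export
render_context <- function(array = build_retinal_array(),
                           light = light_source(),
                           baseline = 0.06, sigma_freq = NULL,
                           lesion = lesion_config("none")) {
  structure(list(array = array, light = light, baseline = baseline,
                 sigma_freq = sigma_freq, lesion = lesion),
            class = "render_context")
}

# render the view a policy affords in one room (pre-assembled mesh)
render_policy_view <- function(pol, scene, ctx) {
  render_binocular(pol$pose, pol$eyes, ctx$array, scene, ctx$light,
                   lesion = ctx$lesion, baseline = ctx$baseline,
                   sigma_freq = ctx$sigma_freq)
}

# flatten a binocular image pair for comparison
pair_vec <- function(img) c(img$left, img$right)

validate_belief <- function(belief, library) {
  check_finite(belief, "belief")
  if (length(belief) != length(library$rooms)) {
    stop_invalid("`belief` must have one entry per room")
  }
  if (any(belief < 0) || abs(sum(belief) - 1) > 1e-12) {
    stop_invalid("`belief` entries must be >= 0 and sum to 1")
  }
  as.numeric(belief)
}

#' Predictive outcome distribution of a policy
#'
#' Renders the policy's view in every room with non-zero belief and
#' clusters the resulting image pairs: two renders fall in the same outcome
#' when their maximum absolute pixel difference is at most `tol`. Each
#' cluster's probability is the summed belief of its member rooms. This
#' discretizes `P(y | pi)` into an exact finite outcome alphabet.
#'
#' @param belief probability vector over the library's rooms.
#' @param pol a `policy`.
#' @param library a `room_library`.
#' @param ctx a `render_context`.
#' @param tol clustering tolerance on pixel intensities, >= 0.
#' @return An `outcome_distribution`: list of clusters, each with `images`
#'   (representative `binocular_image`), `prob` and `members` (room
#'   indices); plus the tolerance used.
#' @export
predictive_outcomes <- function(belief, pol, library, ctx, tol = 1e-6) {
  belief <- validate_belief(belief, library)
  if (!is.finite(tol) || tol < 0) stop_invalid("`tol` must be >= 0")
  idx <- which(belief > 0)
  renders <- lapply(idx, function(i) {
    render_policy_view(pol, assemble_room(library$rooms[[i]]), ctx)
  })
  clusters <- list()
  for (k in seq_along(idx)) {
    v <- pair_vec(renders[[k]])
    placed <- FALSE
    for (c_i in seq_along(clusters)) {
      if (max(abs(v - clusters[[c_i]]$vec)) <= tol) {
        clusters[[c_i]]$prob <- clusters[[c_i]]$prob + belief[idx[k]]
        clusters[[c_i]]$members <- c(clusters[[c_i]]$members, idx[k])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1]] <- list(
        images = renders[[k]], vec = v, prob = belief[idx[k]],
        members = idx[k])
    }
  }
  clusters <- lapply(clusters, function(cl) { cl$vec <- NULL; cl })
  structure(list(clusters = clusters, tol = tol),
            class = "outcome_distribution")
}

#' Shannon entropy in bits
#'
#' `-sum(p * log2(p))` with the convention `0 * log 0 = 0`.
#'
#' @param p probability vector (non-negative, sums to 1).
#' @return Entropy in bits.
#' @export
entropy_bits <- function(p) {
  check_finite(p, "p")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop_invalid("`p` must be a probability vector")
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Sensory noise models for ambiguity
#'
#' The renderer itself is deterministic, so the conditional outcome
#' distribution `P(y | room, pi)` is a point mass and the expected
#' ambiguity is exactly 0. `noise_uniform_bins()` describes the opposite
#' extreme -- the eyes-closed channel -- in which each of `n_cells` retinal
#' cells reports one of `K` equiprobable intensity bins regardless of the
#' scene, contributing `n_cells * log2(K)` bits of conditional entropy in
#' every room.
#'
#' @param K number of intensity bins, >= 2.
#' @param n_cells number of cells subjected to the noise.
#' @return A `noise_model`.
#' @export
noise_uniform_bins <- function(K = 16, n_cells = 1) {
  if (K < 2 || n_cells < 1) stop_invalid("need K >= 2 and n_cells >= 1")
  structure(list(kind = "uniform_bins", K = K, n_cells = n_cells),
            class = "noise_model")
}

#' Expected ambiguity of a policy
#'
#' `E_{P(x|pi)} H[P(y|x, pi)]` in bits. With the deterministic renderer and
#' no noise model this is exactly 0; with a [noise_uniform_bins()] model the
#' conditional entropy is the same in every room, so the belief-weighted
#' average equals `n_cells * log2(K)`.
#'
#' @inheritParams predictive_outcomes
#' @param noise a `noise_model` or `NULL` (noiseless).
#' @return Expected ambiguity in bits.
#' @export
expected_ambiguity <- function(belief, pol, library, ctx, noise = NULL) {
  belief <- validate_belief(belief, library)
  if (is.null(noise)) return(0)
  if (!inherits(noise, "noise_model")) {
    stop_invalid("`noise` must be a noise_model or NULL")
  }
  # iid equiprobable bins: H[y | room] = n_cells * log2(K) for every room
  sum(belief[belief > 0]) * noise$n_cells * log2(noise$K)
}

#' Expected information gain of a policy
#'
#' The mutual information between rooms and predicted observations under a
#' policy, computed as predictive entropy minus expected ambiguity. On the
#' discrete outcome table this equals both the expected KL divergence from
#' prior to posterior and the KL divergence of the joint from the product
#' of marginals (see [mutual_information_oracle()]).
#'
#' @inheritParams expected_ambiguity
#' @param tol outcome clustering tolerance.
#' @return Expected information gain in bits (>= 0 up to rounding).
#' @export
expected_information_gain <- function(belief, pol, library, ctx,
                                      tol = 1e-6, noise = NULL) {
  outcomes <- predictive_outcomes(belief, pol, library, ctx, tol)
  probs <- vapply(outcomes$clusters, `[[`, numeric(1), "prob")
  entropy_bits(probs) - expected_ambiguity(belief, pol, library, ctx, noise)
}

#' Joint room-by-outcome table of a policy
#'
#' The discrete joint `P(room, outcome | pi)` implied by a clustered
#' outcome distribution: row `i`, column `c` holds the belief of room `i`
#' if that room is a member of cluster `c`, else 0.
#'
#' @param belief probability vector over rooms.
#' @param outcomes an `outcome_distribution`.
#' @return A rooms x outcomes matrix summing to 1.
#' @export
outcome_joint <- function(belief, outcomes) {
  n_rooms <- length(belief)
  J <- matrix(0, n_rooms, length(outcomes$clusters))
  for (c_i in seq_along(outcomes$clusters)) {
    m <- outcomes$clusters[[c_i]]$members
    J[m, c_i] <- belief[m]
  }
  J
}

#' The three faces of mutual information
#'
#' Brute-force evaluation, on a discrete joint table of causes (rows) by
#' outcomes (columns), of the three algebraically equal expressions of the
#' mutual information: the KL divergence of the joint from the product of
#' its marginals; the outcome-averaged KL divergence from prior to
#' posterior over causes (the information gain); and the predictive entropy
#' of outcomes minus the expected conditional outcome entropy (predictive
#' entropy minus ambiguity). All in bits.
#'
#' @param joint non-negative matrix summing to 1; rows are causes, columns
#'   outcomes.
#' @return Named numeric triple `kl_joint`, `expected_kl`,
#'   `entropy_minus_ambiguity`.
#' @export
mutual_information_oracle <- function(joint) {
  if (!is.matrix(joint) || any(joint < 0) || abs(sum(joint) - 1) > 1e-9) {
    stop_invalid("`joint` must be a non-negative matrix summing to 1")
  }
  px <- rowSums(joint)
  py <- colSums(joint)
  xlog <- function(num, den) {
    i <- num > 0
    sum(num[i] * log2(num[i] / den[i]))
  }
  # 1) KL(joint || outer product of marginals)
  kl_joint <- xlog(joint, outer(px, py))
  # 2) E_{p(y)} KL(p(x|y) || p(x))
  expected_kl <- 0
  for (j in seq_along(py)) {
    if (py[j] > 0) {
      post <- joint[, j] / py[j]
      expected_kl <- expected_kl + py[j] * xlog(post, px)
    }
  }
  # 3) H[p(y)] - sum_x p(x) H[p(y|x)]
  hy <- entropy_bits(py)
  amb <- 0
  for (i in seq_along(px)) {
    if (px[i] > 0) amb <- amb + px[i] * entropy_bits(joint[i, ] / px[i])
  }
  c(kl_joint = kl_joint, expected_kl = expected_kl,
    entropy_minus_ambiguity = hy - amb)
}

#' Rank candidate fixations by salience
#'
#' Scores every policy by predictive entropy, expected ambiguity and
#' expected information gain, and ranks them by descending gain (ties
#' broken by policy label, lexicographically). The most salient fixation --
#' the best next experiment -- is rank 1.
#'
#' @inheritParams expected_information_gain
#' @param policies non-empty list of `policy` objects.
#' @return A `salience_report` data frame with columns `policy`,
#'   `predictive_entropy_bits`, `expected_ambiguity_bits`,
#'   `info_gain_bits`, `rank`.
#' @export
rank_policies <- function(belief, policies, library, ctx, tol = 1e-6,
                          noise = NULL) {
  if (length(policies) == 0) stop_invalid("`policies` must be non-empty")
  belief <- validate_belief(belief, library)
  rows <- lapply(policies, function(pol) {
    outcomes <- predictive_outcomes(belief, pol, library, ctx, tol)
    probs <- vapply(outcomes$clusters, `[[`, numeric(1), "prob")
    pe <- entropy_bits(probs)
    amb <- expected_ambiguity(belief, pol, library, ctx, noise)
    data.frame(policy = pol$label, predictive_entropy_bits = pe,
               expected_ambiguity_bits = amb, info_gain_bits = pe - amb,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  ord <- order(-report$info_gain_bits, report$policy)
  report <- report[ord, , drop = FALSE]
  report$rank <- seq_len(nrow(report))
  rownames(report) <- NULL
  class(report) <- c("salience_report", "data.frame")
  report
}

#' Bayesian belief update from a rendered observation
#'
#' Exact Bayes over rooms with the deterministic renderer as likelihood:
#' the posterior is proportional to the prior times an indicator of whether
#' the room's render under the policy matches the observation within `tol`
#' (max absolute pixel difference over both eyes). Rooms with zero prior
#' stay at zero. An observation consistent with no room is an error, not an
#' all-zero belief.
#'
#' @inheritParams predictive_outcomes
#' @param observed a `binocular_image` (or list with `left`/`right`
#'   matrices) produced under the same render context.
#' @return The posterior probability vector over rooms.
#' @export
update_belief <- function(belief, observed, pol, library, ctx, tol = 1e-6) {
  belief <- validate_belief(belief, library)
  obs <- c(observed$left, observed$right)
  match_room <- function(i) {
    img <- render_policy_view(pol, assemble_room(library$rooms[[i]]), ctx)
    as.numeric(max(abs(pair_vec(img) - obs)) <= tol)
  }
  lik <- numeric(length(belief))
  for (i in which(belief > 0)) lik[i] <- match_room(i)
  post <- belief * lik
  total <- sum(post)
  if (total <= 0) {
    stop_invalid("observation is inconsistent with every room of non-zero belief",
                 class = "activevision_inconsistent_observation")
  }
  post / total
}
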