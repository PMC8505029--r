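#' Simulation design for synthetic item-response data
#'
#' Describes an I-by-N test administration: `n_items` items taken by
#' `n_persons` persons, dichotomous or partial credit, with abilities
#' drawn from a normal population and (step) difficulties spread over a
#' logit range.  Defaults emulate a well-targeted school assessment:
#' ability ~ Normal(0, 1) and difficulties equally spaced on (-2, 2),
#' the regime where persons and items line up on a Wright map.
#'
#' @param n_items Number of items (>= 2).
#' @param n_persons Number of persons (>= 2).
#' @param model `"dichotomous"` or `"pcm"`.
#' @param categories_per_item Max score per item (vector recycled to
#'   `n_items`); forced to 1 for dichotomous.
#' @param theta_mean,theta_sd Ability population parameters (`sd > 0`).
#' @param difficulty_range Length-2 `(low, high)` logit range over which
#'   item locations are equally spaced.
#' @param spacing `"equal"` (equally spaced) or `"uniform"` (drawn
#'   uniformly over the range).
#' @param seed Integer seed; all generators are reproducible under it.
#' @return A `sim_design` list.
#' @export
sim_design <- function(n_items = 20L, n_persons = 500L,
                       model = c("dichotomous", "pcm"),
                       categories_per_item = 1L,
                       theta_mean = 0, theta_sd = 1,
                       difficulty_range = c(-2, 2),
                       spacing = c("equal", "uniform"),
                       seed = 1L) {
  model <- match.arg(model); spacing <- match.arg(spacing)
  stopifnot(n_items >= 2, n_persons >= 2, theta_sd > 0,
            length(difficulty_range) == 2L,
            difficulty_range[1] < difficulty_range[2])
  cats <- rep_len(as.integer(categories_per_item), n_items)
  if (model == "dichotomous") cats <- rep(1L, n_items)
  stopifnot(all(cats >= 1L))
  structure(list(n_items = as.integer(n_items), n_persons = as.integer(n_persons),
                 model = model, categories_per_item = cats,
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 difficulty_range = difficulty_range, spacing = spacing,
                 seed = as.integer(seed)),
            class = "sim_design")
}

# item locations over the design range; steps of a polytomous item are
# centred on the location and spread +/- 0.5 logits per step
sim_true_delta <- function(design) {
  I <- design$n_items
  loc <- switch(design$spacing,
                equal = seq(design$difficulty_range[1], design$difficulty_range[2],
                            length.out = I),
                uniform = sort(runif(I, design$difficulty_range[1], design$difficulty_range[2])))
  purrr::map_dfr(seq_len(I), function(i) {
    m <- design$categories_per_item[i]
    st <- if (m == 1L) loc[i] else loc[i] + seq(-0.5 * (m - 1), 0.5 * (m - 1), length.out = m)
    tibble::tibble(item_id = sprintf("I%04d", i), step = seq_len(m), delta = st)
  })
}

# draw one response per person/item from the PCM category distribution
sim_draw <- function(theta, delta_tbl) {
  ids <- unique(delta_tbl$item_id)
  Y <- matrix(NA_real_, length(theta), length(ids), dimnames = list(NULL, ids))
  for (id in ids) {
    st <- delta_tbl$delta[delta_tbl$item_id == id]
    p <- pcm_category_probabilities(theta, st)
    u <- runif(length(theta))
    Y[, id] <- max.col(u < t(apply(p, 1L, cumsum)), ties.method = "first") - 1L
  }
  Y
}

#' Generate synthetic item responses
#'
#' Draws abilities from the design's normal population, fixes true
#' (step) difficulties over the design range, and samples responses
#' from the dichotomous Rasch or partial-credit category distribution.
#' Deterministic under the design seed.
#'
#' @param design A [sim_design()].
#' @return List: `responses` ([response_matrix()]), `true_theta`
#'   (vector), `true_delta` (tibble `item_id`, `step`, `delta`).
#' @examples
#' sim <- sim_responses(sim_design(n_items = 5, n_persons = 50, seed = 42))
#' sim$responses
#' @export
sim_responses <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  withr_seed(design$seed)
  theta <- rnorm(design$n_persons, design$theta_mean, design$theta_sd)
  delta <- sim_true_delta(design)
  Y <- sim_draw(theta, delta)
  rmx <- new_response_matrix(Y, as.character(seq_len(nrow(Y))), colnames(Y),
                             declared_max = stats::setNames(
                               vapply(split(delta$step, delta$item_id), max, numeric(1))[colnames(Y)],
                               colnames(Y)))
  list(responses = rmx, true_theta = theta, true_delta = delta)
}

withr_seed <- function(seed) set.seed(as.integer(seed))

#' Generate grouped responses with injected differential item functioning
#'
#' Two groups with identical ability distributions; on the chosen items
#' the focal (second) group faces a difficulty shifted by `+dif_size/2`
#' and the reference group by `-dif_size/2` (symmetric injection so the
#' sum-to-zero interaction decomposition recovers `+/- dif_size/2` per
#' group).  Positive `dif_size` makes the items *harder* for the focal
#' group.
#'
#' @param design A [sim_design()].
#' @param dif_items Integer indices of items carrying DIF.
#' @param dif_size DIF magnitude in logits.
#' @param group_split Proportion of persons in the reference group.
#' @return A [grouped_responses()] object with groups `"1"` (reference)
#'   and `"2"` (focal); attributes `true_theta` and `true_delta`.
#' @export
sim_dif_data <- function(design, dif_items = integer(), dif_size = 0,
                         group_split = 0.5) {
  stopifnot(inherits(design, "sim_design"))
  if (length(dif_items) == 0L && dif_size != 0) {
    abort("dif_size != 0 requires a non-empty dif_items set")
  }
  stopifnot(all(dif_items >= 1L), all(dif_items <= design$n_items),
            group_split > 0, group_split < 1)
  withr_seed(design$seed)
  N <- design$n_persons
  n_ref <- round(group_split * N)
  group <- c(rep("1", n_ref), rep("2", N - n_ref))
  theta <- rnorm(N, design$theta_mean, design$theta_sd)
  delta <- sim_true_delta(design)
  ids <- unique(delta$item_id)
  shift_ref <- delta; shift_foc <- delta
  dif_ids <- ids[dif_items]
  shift_ref$delta[shift_ref$item_id %in% dif_ids] <-
    shift_ref$delta[shift_ref$item_id %in% dif_ids] - dif_size / 2
  shift_foc$delta[shift_foc$item_id %in% dif_ids] <-
    shift_foc$delta[shift_foc$item_id %in% dif_ids] + dif_size / 2
  Y <- matrix(NA_real_, N, length(ids), dimnames = list(NULL, ids))
  Y[group == "1", ] <- sim_draw(theta[group == "1"], shift_ref)
  Y[group == "2", ] <- sim_draw(theta[group == "2"], shift_foc)
  df <- dplyr::bind_cols(tibble::tibble(group = group), tibble::as_tibble(Y))
  out <- grouped_responses(df)
  attr(out, "true_theta") <- theta
  attr(out, "true_delta") <- delta
  out
}

#' Generate two linked test forms sharing anchor items
#'
#' The last `n_link` items of Form A reappear as the first `n_link`
#' items of Form B with identical labels and identical true
#' difficulties; the remaining items are form-specific.  The Form B
#' ability distribution may differ from Form A's (e.g. a higher mean for
#' an older cohort), which is exactly the situation fixed-anchor
#' equating resolves.
#'
#' @param designA,designB [sim_design()]s for the two forms.
#' @param n_link Number of shared link items (>= 2).
#' @return List: `formA`, `formB` ([response_matrix()]s),
#'   `link_items` (labels), `true_delta_A`, `true_delta_B`,
#'   `true_theta_A`, `true_theta_B`.
#' @export
sim_linked_forms <- function(designA, designB, n_link = 10L) {
  stopifnot(inherits(designA, "sim_design"), inherits(designB, "sim_design"))
  if (n_link < 2L) abort("equating is undefined with fewer than 2 link items")
  stopifnot(n_link <= designA$n_items, n_link <= designB$n_items)
  withr_seed(designA$seed)
  thA <- rnorm(designA$n_persons, designA$theta_mean, designA$theta_sd)
  dA <- sim_true_delta(designA)
  # relabel the hardest n_link Form A items as the shared links
  link_ids <- sprintf("L%03d", seq_len(n_link))
  old <- tail(unique(dA$item_id), n_link)
  dA$item_id <- paste0("A", dA$item_id)
  for (k in seq_len(n_link)) dA$item_id[dA$item_id == paste0("A", old[k])] <- link_ids[k]
  YA <- sim_draw(thA, dA)

  set.seed(designB$seed + 1L)
  thB <- rnorm(designB$n_persons, designB$theta_mean, designB$theta_sd)
  dB <- sim_true_delta(designB)
  dB$item_id <- paste0("B", dB$item_id)
  # links keep their true Form A difficulties; B-specific items fill the rest
  keepB <- dB[dB$item_id %in% unique(dB$item_id)[seq_len(designB$n_items - n_link)], ]
  dB_all <- dplyr::bind_rows(dA[dA$item_id %in% link_ids, ], keepB)
  YB <- sim_draw(thB, dB_all)
  list(
    formA = new_response_matrix(YA, as.character(seq_len(nrow(YA))), colnames(YA)),
    formB = new_response_matrix(YB, as.character(seq_len(nrow(YB))), colnames(YB)),
    link_items = link_ids,
    true_delta_A = dA, true_delta_B = dB_all,
    true_theta_A = thA, true_theta_B = thB
  )
}

#' Generate a subject-by-rater score table with known reliability
#'
#' One-way random-effects model: `x_sr = mu + b_s + e_sr` with
#' `b_s ~ N(0, icc)` and `e_sr ~ N(0, 1 - icc)`, so the population
#' single-rater intraclass correlation equals `true_icc`.
#'
#' @param n_subjects Number of subjects (>= 5).
#' @param n_raters Number of raters (>= 2).
#' @param true_icc Target single-rater ICC in `[0, 1)`.
#' @param seed Integer seed.
#' @return Tibble with `subject` plus one column per rater.
#' @export
sim_rater_table <- function(n_subjects = 100L, n_raters = 3L, true_icc = 0.8,
                            seed = 1L) {
  stopifnot(n_subjects >= 5L, n_raters >= 2L)
  if (true_icc < 0 || true_icc >= 1) abort("true_icc must lie in [0, 1)")
  withr_seed(seed)
  b <- rnorm(n_subjects, 0, sqrt(true_icc))
  e <- matrix(rnorm(n_subjects * n_raters, 0, sqrt(1 - true_icc)), n_subjects)
  x <- sweep(e, 1L, b, `+`)
  colnames(x) <- paste0("R", seq_len(n_raters))
  dplyr::bind_cols(tibble::tibble(subject = seq_len(n_subjects)), tibble::as_tibble(x))
}
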