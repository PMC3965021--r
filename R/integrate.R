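# Integration of data-specific LLS networks by rank-decay weighted summation.

#' Weighted sum of per-data-type LLS values
#'
#' Sorts the values in decreasing order as `L0 >= L1 >= ... >= Ln` and
#' returns
#' \deqn{WS = L_0 + \sum_{i \ge 1} \frac{L_i}{D \cdot i}}
#' (linear rank decay), or `L0 + sum(Li / D^i)` when `decay = "geometric"`.
#' The free parameter `D >= 1` controls how much weaker lines of evidence
#' contribute beyond the single best one: `D = 1` leaves the harmonic decay
#' alone, and as `D` grows the sum approaches `L0`.
#'
#' @param lls_values Nonempty numeric vector, one LLS per evidence type.
#' @param D Decay parameter, >= 1.
#' @param decay `"linear"` (default) or `"geometric"`.
#' @return The weighted sum.
#' @examples
#' weighted_sum(c(3, 2, 1), D = 2)  # 3 + 2/2 + 1/4 = 4.25
#' @export
weighted_sum <- function(lls_values, D, decay = c("linear", "geometric")) {
  decay <- match.arg(decay)
  if (!length(lls_values)) stop("weighted_sum of an empty list is undefined", call. = FALSE)
  stopifnot(D >= 1)
  v <- sort(as.numeric(lls_values), decreasing = TRUE)
  i <- seq_along(v) - 1L
  w <- if (decay == "linear") c(1, 1 / (D * i[-1L])) else 1 / D^i
  sum(v * w)
}

#' Integrate data-specific networks into one weighted network
#'
#' For every gene pair present in at least one input network, the
#' per-data-type LLS values (at most one per tag) are combined with
#' [weighted_sum()]; the pair is retained when the sum reaches the
#' threshold `T`. Multiple datasets of one evidence type should be
#' pre-integrated within-type (with the same function) before entering
#' cross-type integration, so each tag contributes a single value.
#'
#' @param nets List of [fl_network] objects with distinct tags.
#' @param D Decay parameter passed to [weighted_sum()].
#' @param T_ Minimum weighted sum for edge retention (default 0: retain
#'   any pair whose integrated log-odds are positive).
#' @param decay Decay form, see [weighted_sum()].
#' @return A [fl_network] tagged `"integrated"`, with `D`, `T` and the
#'   decay form recorded in attributes.
#' @export
integrate_networks <- function(nets, D = 1, T_ = 0, decay = c("linear", "geometric")) {
  decay <- match.arg(decay)
  stopifnot(length(nets) >= 1L, D >= 1, !is.na(T_), T_ < Inf)
  if (!all(vapply(nets, inherits, TRUE, "fl_network"))) {
    stop("all inputs must be fl_network objects", call. = FALSE)
  }
  tags <- vapply(nets, network_tag, "")
  if (anyDuplicated(tags)) {
    stop("duplicate data-type tags among inputs: ", tags[duplicated(tags)][1],
         "; pre-integrate within-type first", call. = FALSE)
  }
  a <- unlist(lapply(nets, `[[`, "a"), use.names = FALSE)
  b <- unlist(lapply(nets, `[[`, "b"), use.names = FALSE)
  w <- unlist(lapply(nets, `[[`, "weight"), use.names = FALSE)
  key <- pair_key(a, b)
  # per-pair weighted sum over its per-tag LLS values, order-independent
  ws <- vapply(split(w, key), weighted_sum, 0, D = D, decay = decay)
  keep <- ws >= T_
  ab <- strsplit(names(ws)[keep], "\r", fixed = TRUE)
  out <- fl_network(vapply(ab, `[[`, "", 1L), vapply(ab, `[[`, "", 2L),
                    unname(ws[keep]), tag = "integrated")
  attr(out, "D") <- D
  attr(out, "T") <- T_
  attr(out, "decay") <- decay
  out
}

#' Tune the decay parameter on a held-out gold standard
#'
#' Integrates the networks at each candidate `D` and scores the result by
#' the area under its cumulative precision-recall curve against a
#' validation gold standard (which the caller must keep disjoint from the
#' gold standard used for calibration). Returns the grid value with the
#' largest PR area; ties go to the smallest `D`.
#'
#' @param nets List of [fl_network] objects.
#' @param gold_validate A [gold_standard] independent of calibration.
#' @param grid Nonempty numeric vector of candidate `D` values (all >= 1).
#' @param T_ Retention threshold used at every grid point.
#' @param bin_size,genome_size Passed to [pr_curve()].
#' @return The selected `D`.
#' @export
tune_D <- function(nets, gold_validate, grid, T_ = 0,
                   bin_size = 1000L, genome_size = NULL) {
  stopifnot(length(grid) >= 1L, all(grid >= 1))
  if (is.null(genome_size)) {
    genome_size <- length(unique(unlist(lapply(nets, network_genes))))
  }
  grid <- sort(grid)
  areas <- vapply(grid, function(D) {
    net <- integrate_networks(nets, D = D, T_ = T_)
    if (!nrow(net)) return(NA_real_)
    pr <- tryCatch(pr_curve(net, gold_validate, bin_size = bin_size,
                            genome_size = genome_size),
                   error = function(e) NULL)
    if (is.null(pr)) NA_real_ else pr_area(pr)
  }, 0)
  if (all(is.na(areas))) {
    stop("no gold-evaluable integrated edges at any grid value", call. = FALSE)
  }
  grid[which.max(areas)]  # which.max takes the first (smallest D) on ties
}
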