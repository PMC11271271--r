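#' Build the co-activity graph of an MEA recording
#'
#' Channels are nodes; two channels are connected by an (unweighted,
#' deduplicated) edge if they both fire at least one spike in the same
#' 200-ms bin. Bins partition `[0, duration)` half-open. All recorded
#' channels are nodes by default (silent channels included), since the
#' synchrony statistic divides by the total node count; pass
#' `channels` to restrict the node set.
#'
#' @param trains Spike-train list (as from [detect_spikes()]).
#' @param duration_s Recording duration (s), > 0.
#' @param bin_width_s Bin width (s), > 0 (default 0.2).
#' @param channels Optional node subset (channel ids).
#' @return Object of class `activity_graph`: `nodes` (channel ids),
#'   `edges` (two-column matrix, each row an unordered pair), `n_bins`,
#'   `bin_width_s`.
#' @examples
#' tr <- list(list(channel = 1, spike_times_s = 0.05),
#'            list(channel = 2, spike_times_s = 0.1),
#'            list(channel = 3, spike_times_s = 0.15))
#' g <- build_coactivity_graph(tr, duration_s = 1)
#' nrow(g$edges)  # triangle
#' @export
build_coactivity_graph <- function(trains, duration_s, bin_width_s = 0.2,
                                   channels = NULL) {
  stop_if_not_scalar(duration_s, "duration_s")
  stop_if_not_scalar(bin_width_s, "bin_width_s")
  if (duration_s <= 0 || bin_width_s <= 0) {
    stop("duration_s and bin_width_s must be > 0", call. = FALSE)
  }
  ids <- vapply(trains, function(tr) as.integer(tr$channel), integer(1))
  if (is.null(channels)) channels <- ids
  n_bins <- max(1L, ceiling(duration_s / bin_width_s))
  keep <- match(channels, ids)
  ## channel x bin incidence
  B <- matrix(FALSE, nrow = length(channels), ncol = n_bins)
  for (k in seq_along(keep)) {
    st <- trains[[keep[k]]]$spike_times_s
    st <- st[st >= 0 & st < duration_s]
    if (length(st)) B[k, unique(floor(st / bin_width_s) + 1L)] <- TRUE
  }
  shared <- tcrossprod(B * 1)          # pairwise shared-bin counts
  adj <- shared > 0
  diag(adj) <- FALSE
  pairs <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- cbind(channels[pairs[, 1L]], channels[pairs[, 2L]])
  colnames(edges) <- c("a", "b")
  structure(list(nodes = channels, edges = edges, n_bins = n_bins,
                 bin_width_s = bin_width_s),
            class = "activity_graph")
}

#' @export
print.activity_graph <- function(x, ...) {
  cat(sprintf("<activity_graph> %d nodes, %d edges (%g-s bins, %d bins)\n",
              length(x$nodes), nrow(x$edges), x$bin_width_s, x$n_bins))
  invisible(x)
}

#' Mean degree centrality of a co-activity graph
#'
#' The study's synchrony statistic. The `"paper_formula"` variant is
#' 2E/N (the degree sum over the node count; each edge counted once per
#' endpoint), which ranges up to N-1. The `"normalized"` variant is the
#' mean over nodes of degree/(N-1), the convention of standard graph
#' libraries, ranging up to 1. The printed formula conflicts with the
#' magnitudes usually reported for normalized centrality, so both are
#' provided; `"paper_formula"` is the default.
#'
#' @param graph An `activity_graph`.
#' @param variant `"paper_formula"` or `"normalized"`.
#' @return Dimensionless scalar.
#' @examples
#' tr <- list(list(channel = 1, spike_times_s = 0.05),
#'            list(channel = 2, spike_times_s = 0.1))
#' g <- build_coactivity_graph(tr, duration_s = 1)
#' mean_degree_centrality(g)           # 2*1/2 = 1
#' mean_degree_centrality(g, "normalized")
#' @export
mean_degree_centrality <- function(graph,
                                   variant = c("paper_formula", "normalized")) {
  stopifnot(inherits(graph, "activity_graph"))
  variant <- match.arg(variant)
  n <- length(graph$nodes)
  if (n < 1L) stop("graph has no nodes", call. = FALSE)
  e <- nrow(graph$edges)
  if (variant == "paper_formula") return(2 * e / n)
  if (n == 1L) return(0)
  deg <- table(factor(c(graph$edges[, 1L], graph$edges[, 2L]),
                      levels = graph$nodes))
  mean(as.numeric(deg) / (n - 1L))
}
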