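#' Partition markers into linkage groups
#'
#' Single-linkage (transitive-closure) grouping: two markers join the same
#' group whenever they are connected by a chain of pairs each satisfying
#' both `lod >= lod_min` and `r_hat <= r_max`. Pairs absent from `pairwise`
#' are treated as unlinked. Group ids are assigned by descending group size,
#' ties by smallest member id; the result is invariant to marker input
#' order.
#'
#' @param pairwise Data frame as produced by [pairwise_estimates()]
#'   (columns `marker_i`, `marker_j`, `r_hat`, `lod`).
#' @param lod_min Minimum LOD for a pair to count as linked.
#' @param r_max Maximum recombination fraction for a pair to count as linked.
#' @param markers Optional character vector of all marker ids (defaults to
#'   those appearing in `pairwise`); markers without any linked pair come
#'   back as singleton groups.
#' @return List of character vectors, one per linkage group.
#' @export
group_markers <- function(pairwise, lod_min = 1.0, r_max = 0.4,
                          markers = NULL) {
  if (is.null(markers)) {
    markers <- unique(c(pairwise$marker_i, pairwise$marker_j))
  }
  markers <- sort(unique(as.character(markers)))
  if (length(markers) == 0L) return(list())
  linked <- !is.na(pairwise$r_hat) & !is.na(pairwise$lod) &
    pairwise$lod >= lod_min & pairwise$r_hat <= r_max
  edges <- pairwise[linked, c("marker_i", "marker_j"), drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = markers))
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  groups <- lapply(groups, sort)
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, function(x) x[1], character(1)))
  unname(groups[ord])
}

# pairwise Kosambi distance lookup matrix for one group of markers;
# r >= 0.5 (and missing pairs) are clamped to 0.4999
.distance_matrix <- function(markers, pairwise, clamp = 0.4999) {
  k <- length(markers)
  D <- base::matrix(kosambi(clamp), k, k, dimnames = list(markers, markers))
  diag(D) <- 0
  sel <- pairwise$marker_i %in% markers & pairwise$marker_j %in% markers
  pw <- pairwise[sel, , drop = FALSE]
  r <- pmin(ifelse(is.na(pw$r_hat), clamp, pw$r_hat), clamp)
  d <- kosambi(r)
  D[cbind(pw$marker_i, pw$marker_j)] <- d
  D[cbind(pw$marker_j, pw$marker_i)] <- d
  D
}

.sarf <- function(order, D) sum(D[cbind(order[-length(order)], order[-1L])])

# canonical orientation: lexicographically smaller terminal marker first
.canonical <- function(ord) {
  if (length(ord) > 1L && ord[length(ord)] < ord[1L]) rev(ord) else ord
}

#' Order markers within a linkage group
#'
#' Seriation by minimizing the sum of adjacent recombination-fraction
#' distances (SARF, in Kosambi cM): the chain is seeded with the pair at the
#' largest finite distance, remaining markers are inserted greedily at the
#' position minimizing the SARF increase (ties broken by marker id), and
#' 2-opt segment reversals are applied until no improvement remains. The
#' orientation is canonicalized so the lexicographically smaller terminal
#' marker comes first.
#'
#' @param group Character vector of marker ids (one linkage group).
#' @param pairwise Data frame of two-point estimates (see
#'   [pairwise_estimates()]). Adjacent `r_hat >= 0.5` and missing pairs are
#'   clamped to 0.4999.
#' @return Character vector: the ordered markers.
#' @export
order_group <- function(group, pairwise) {
  group <- as.character(group)
  if (length(group) <= 2L) return(.canonical(sort(group)))
  D <- .distance_matrix(group, pairwise)
  k <- length(group)
  # seed: the pair at the largest distance (likely the two chromosome ends);
  # ties resolved toward smaller marker ids via column-major which()
  seed <- which(D == max(D), arr.ind = TRUE)[1L, ]
  ord <- sort(group[seed])
  rest <- setdiff(group, ord)
  while (length(rest)) {
    best <- NULL
    for (m in rest) {  # rest stays sorted: ties fall to the smaller id
      for (pos in 0:length(ord)) {
        cand <- append(ord, m, after = pos)
        s <- .sarf(cand, D)
        if (is.null(best) || s < best$s - 1e-12) best <- list(m = m, s = s, ord = cand)
      }
    }
    ord <- best$ord
    rest <- setdiff(rest, best$m)
  }
  # 2-opt: reverse internal segments while SARF improves
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    s0 <- .sarf(ord, D)
    for (i in 1:(k - 1L)) {
      for (j in (i + 1L):k) {
        cand <- ord
        cand[i:j] <- rev(cand[i:j])
        s <- .sarf(cand, D)
        if (s < s0 - 1e-12) {
          ord <- cand
          s0 <- s
          improved <- TRUE
        }
      }
    }
  }
  .canonical(ord)
}

#' Build a genetic map from ordered linkage groups
#'
#' Assigns cumulative Kosambi positions: the position of each marker is the
#' running sum of `kosambi(r_hat)` over adjacent ordered pairs, starting at
#' 0. Adjacent pairs with `r_hat >= 0.5` (or with no estimate) are clamped
#' to 0.4999 with a warning.
#'
#' @param groups List of ordered marker-id vectors (see [order_group()]).
#' @param pairwise Data frame of two-point estimates.
#' @param provenance Optional list of metadata (thresholds, seed) stored as
#'   an attribute.
#' @return Object of class `genetic_map`: data frame with columns `group`
#'   (integer), `marker`, `pos_cM`.
#' @export
build_map <- function(groups, pairwise, provenance = list()) {
  if (is.character(groups)) groups <- list(groups)
  rlook <- new.env(parent = emptyenv())
  key <- function(a, b) paste(a, b, sep = "\r")
  assign_all <- function() {
    for (i in seq_len(nrow(pairwise))) {
      assign(key(pairwise$marker_i[i], pairwise$marker_j[i]),
             pairwise$r_hat[i], envir = rlook)
      assign(key(pairwise$marker_j[i], pairwise$marker_i[i]),
             pairwise$r_hat[i], envir = rlook)
    }
  }
  assign_all()
  clamped <- 0L
  rows <- lapply(seq_along(groups), function(gi) {
    ord <- as.character(groups[[gi]])
    if (length(ord) == 1L) {
      return(data.frame(group = gi, marker = ord, pos_cM = 0,
                        stringsAsFactors = FALSE))
    }
    r_adj <- vapply(seq_len(length(ord) - 1L), function(i) {
      v <- mget(key(ord[i], ord[i + 1L]), envir = rlook,
                ifnotfound = NA_real_)[[1L]]
      v
    }, numeric(1))
    bad <- is.na(r_adj) | r_adj >= 0.5
    clamped <<- clamped + sum(bad)
    r_adj[bad] <- 0.4999
    data.frame(group = gi, marker = ord,
               pos_cM = c(0, cumsum(kosambi(r_adj))),
               stringsAsFactors = FALSE)
  })
  if (clamped > 0L) {
    warning(clamped, " adjacent pair(s) had r >= 0.5 or no estimate; clamped to 0.4999")
  }
  map <- do.call(rbind, rows)
  attr(map, "provenance") <- provenance
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @export
print.genetic_map <- function(x, ...) {
  lg <- group_lengths(x)
  cat(sprintf("genetic_map: %d markers in %d linkage groups, summed length %.1f cM\n",
              nrow(x), nrow(lg), sum(lg$length_cM)))
  invisible(x)
}

#' Per-group lengths and marker counts
#'
#' @param map A `genetic_map`.
#' @return Data frame with columns `group`, `length_cM` (last position,
#'   `L_i`) and `n_markers` (`m_i`).
#' @export
group_lengths <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  agg <- do.call(rbind, lapply(split(map, map$group), function(g) {
    data.frame(group = g$group[1], length_cM = max(g$pos_cM),
               n_markers = nrow(g))
  }))
  rownames(agg) <- NULL
  agg[order(agg$group), ]
}

#' Confirm linkage groups with a non-recombinant backcross
#'
#' In a backcross through the achiasmatic sex, every individual inherits
#' each maternal chromosome whole, so all of an individual's calls within a
#' true linkage group must be identical (`AA` or `AB`). A group is
#' consistent when every individual's within-group mismatch rate (calls
#' disagreeing with that individual's majority call) is at most
#' `max_mismatch_rate`. `BB` calls are impossible under the cross; they
#' trigger a warning and always count as mismatches.
#'
#' Distinct groups on the same chromosome co-segregate perfectly, so group
#' pairs whose per-individual inheritance vectors are identical across all
#' individuals are flagged as possibly same-chromosome; pairwise
#' co-segregation correlations are reported.
#'
#' @param map A `genetic_map`.
#' @param nrbc A [genotype_matrix()] from the non-recombinant backcross
#'   (codes `AA`, `AB`, missing).
#' @param max_mismatch_rate Tolerated per-individual mismatch rate within a
#'   group.
#' @return List with `groups` (per-group consistency table), `pairs`
#'   (pairwise co-segregation), `flagged_pairs` (possibly same-chromosome)
#'   and `all_consistent`.
#' @export
confirm_with_nrbc <- function(map, nrbc, max_mismatch_rate = 0) {
  stopifnot(inherits(map, "genetic_map"))
  if (any(nrbc == "BB", na.rm = TRUE)) {
    warning("BB calls present in non-recombinant backcross (impossible under the cross); treated as mismatches")
  }
  groups <- split(map$marker, map$group)
  n_ind <- ncol(nrbc)
  inherit <- base::matrix(NA_character_, length(groups), n_ind,
                          dimnames = list(names(groups), colnames(nrbc)))
  res <- data.frame(group = as.integer(names(groups)), n_markers = NA_integer_,
                    max_mismatch = NA_real_, consistent = NA)
  for (gi in seq_along(groups)) {
    mk <- intersect(groups[[gi]], rownames(nrbc))
    res$n_markers[gi] <- length(mk)
    if (length(mk) == 0L) next
    sub <- nrbc[mk, , drop = FALSE]
    rates <- vapply(seq_len(n_ind), function(j) {
      calls <- sub[, j]
      calls <- calls[!is.na(calls)]
      if (length(calls) == 0L) return(0)
      valid <- calls[calls %in% c("AA", "AB")]
      if (length(valid) == 0L) return(1)
      maj <- names(which.max(table(valid)))
      inherit[gi, j] <<- maj
      mean(calls != maj)
    }, numeric(1))
    res$max_mismatch[gi] <- max(rates)
    res$consistent[gi] <- all(rates <= max_mismatch_rate)
  }
  pairs <- NULL
  if (length(groups) >= 2L) {
    idx <- utils::combn(seq_along(groups), 2L)
    pairs <- data.frame(group_i = as.integer(names(groups))[idx[1L, ]],
                        group_j = as.integer(names(groups))[idx[2L, ]],
                        correlation = NA_real_, identical = FALSE)
    for (k in seq_len(ncol(idx))) {
      a <- inherit[idx[1L, k], ] == "AB"
      b <- inherit[idx[2L, k], ] == "AB"
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) >= 2L && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0) {
        pairs$correlation[k] <- stats::cor(a[ok], b[ok])
      }
      pairs$identical[k] <- sum(ok) > 0L && all(a[ok] == b[ok])
    }
  }
  list(groups = res, pairs = pairs,
       flagged_pairs = if (is.null(pairs)) NULL else
         pairs[pairs$identical, c("group_i", "group_j")],
       all_consistent = all(res$consistent, na.rm = TRUE))
}
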