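#' AHA 16-segment left-ventricular model utilities
#'
#' The left ventricle is divided into 6 basal (1-6), 6 mid-cavity (7-12) and
#' 4 apical (13-16) segments; the apical cap is excluded. Adjacency is defined
#' as ring adjacency within each level plus radial alignment between levels,
#' mimicking the spatial footprint of a coronary-territory lesion.
#'
#' @return `aha_segment_adjacency()` returns a named list mapping each segment
#'   (as character "1".."16") to the integer vector of its neighbours.
#' @export
#' @examples
#' aha_segment_adjacency()[["1"]]
aha_segment_adjacency <- function() {
  adj <- vector("list", 16)
  ring <- function(ids) {
    k <- length(ids)
    lapply(seq_len(k), function(i) ids[c(if (i == 1) k else i - 1,
                                         if (i == k) 1 else i + 1)])
  }
  for (lvl in list(1:6, 7:12, 13:16)) {
    nb <- ring(lvl)
    for (i in seq_along(lvl)) adj[[lvl[i]]] <- c(adj[[lvl[i]]], nb[[i]])
  }
  # basal <-> mid alignment (same wall)
  for (i in 1:6) {
    adj[[i]] <- c(adj[[i]], i + 6L)
    adj[[i + 6L]] <- c(adj[[i + 6L]], i)
  }
  # mid <-> apical alignment: anterior 13~7, septal 14~8/9,
  # inferior 15~10, lateral 16~11/12
  apical_map <- list(`13` = 7L, `14` = c(8L, 9L), `15` = 10L, `16` = c(11L, 12L))
  for (a in names(apical_map)) {
    ai <- as.integer(a)
    for (m in apical_map[[a]]) {
      adj[[ai]] <- c(adj[[ai]], m)
      adj[[m]] <- c(adj[[m]], ai)
    }
  }
  stats::setNames(lapply(adj, function(x) sort(unique(x))), as.character(1:16))
}

# grow a contiguous lesion mask of n_segments starting from a random seed
# segment, breadth-first over the adjacency graph; deterministic given the
# RNG state
grow_lesion_mask <- function(n_segments, adjacency = aha_segment_adjacency()) {
  stopifnot(n_segments >= 1, n_segments <= 16)
  seed_seg <- sample.int(16L, 1L)
  selected <- seed_seg
  frontier <- adjacency[[seed_seg]]
  while (length(selected) < n_segments) {
    frontier <- setdiff(frontier, selected)
    if (length(frontier) == 0L) frontier <- setdiff(1:16, selected)
    nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    selected <- c(selected, nxt)
    frontier <- c(frontier, adjacency[[nxt]])
  }
  mask <- rep(FALSE, 16)
  mask[selected] <- TRUE
  mask
}
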