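#' The AHA 16-segment model of the left ventricle
#'
#' Returns one row per segment: id 1-16, anatomical name, short-axis level
#' (basal segments 1-6, mid 7-12, apical 13-16), the number of angular
#' sectors at that level (6 basal/mid, 4 apical), the within-level sector
#' index, and the angular span `[angle_from, angle_to)` in radians measured
#' counterclockwise (viewed from the apex) from the anterior interventricular
#' groove.
#'
#' @return A tibble with 16 rows.
#' @examples
#' aha_segments()
#' @export
aha_segments <- function() {
  nm <- c("basal anterior", "basal anteroseptal", "basal inferoseptal",
          "basal inferior", "basal inferolateral", "basal anterolateral",
          "mid anterior", "mid anteroseptal", "mid inferoseptal",
          "mid inferior", "mid inferolateral", "mid anterolateral",
          "apical anterior", "apical septal", "apical inferior",
          "apical lateral")
  level <- rep(c("basal", "mid", "apical"), times = c(6, 6, 4))
  n_sectors <- ifelse(level == "apical", 4L, 6L)
  sector <- c(1:6, 1:6, 1:4)
  width <- 2 * pi / n_sectors
  tibble(
    segment_id = 1:16,
    name = nm,
    level = level,
    n_sectors = n_sectors,
    sector = sector,
    angle_from = (sector - 1) * width,
    angle_to = sector * width
  )
}

# adjacency list over the 16 segments: ring neighbours within a level,
# same-sector neighbours between basal and mid, and angular-overlap
# neighbours between mid and apical
aha_adjacency <- function() {
  seg <- aha_segments()
  adj <- lapply(1:16, function(i) integer(0))
  add <- function(a, b) {
    adj[[a]] <<- union(adj[[a]], b)
    adj[[b]] <<- union(adj[[b]], a)
  }
  for (lev in c("basal", "mid", "apical")) {
    ids <- seg$segment_id[seg$level == lev]
    k <- length(ids)
    for (j in seq_len(k)) add(ids[j], ids[j %% k + 1])
  }
  for (s in 1:6) add(s, s + 6L)
  mid <- seg[seg$level == "mid", ]
  api <- seg[seg$level == "apical", ]
  for (i in seq_len(nrow(mid))) {
    for (j in seq_len(nrow(api))) {
      lo <- max(mid$angle_from[i], api$angle_from[j])
      hi <- min(mid$angle_to[i], api$angle_to[j])
      if (hi - lo > 1e-9) add(mid$segment_id[i], api$segment_id[j])
    }
  }
  adj
}

# grow a contiguous defect region of the requested extent
grow_defect_region <- function(extent, adjacency = aha_adjacency()) {
  extent <- max(1L, min(16L, as.integer(extent)))
  region <- sample.int(16L, 1L)
  while (length(region) < extent) {
    frontier <- setdiff(unique(unlist(adjacency[region])), region)
    if (length(frontier) == 0) break
    region <- c(region, frontier[sample.int(length(frontier), 1L)])
  }
  sort(region)
}
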