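#' Build a comet cell object from positions and intensities
#'
#' A comet cell is a one-dimensional intensity profile along the
#' electrophoresis axis: bin positions in um (recorded at the bin's trailing
#' edge), non-negative intensity per bin, and the position of the head/tail
#' boundary.
#'
#' @param position numeric vector of bin positions (um), increasing.
#' @param intensity non-negative intensity per bin; total must be positive.
#' @param head_boundary boundary position (um) separating head from tail,
#'   within the axis range.
#' @return An object of class `comet_cell`.
#' @export
comet_cell <- function(position, intensity, head_boundary) {
  if (length(position) != length(intensity)) {
    stop("position and intensity must have equal length", call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (sum(intensity) <= 0) stop("total intensity must be positive", call. = FALSE)
  if (head_boundary < min(position) - max(diff(c(0, position))) ||
      head_boundary > max(position)) {
    stop("head boundary outside the axis range", call. = FALSE)
  }
  structure(list(position = position, intensity = intensity,
                 head_boundary = head_boundary), class = "comet_cell")
}

# reconstruct comet_cell objects from a serialized cell table row
parse_comet_row <- function(row) {
  int <- as.numeric(strsplit(row$profile, ";", fixed = TRUE)[[1]])
  comet_cell(position = seq_along(int) * row$bin_um,
             intensity = int,
             head_boundary = row$head_boundary_um)
}

#' Per-cell comet endpoints
#'
#' From the intensity profile: tail intensity is the above-background
#' intensity beyond the head boundary; tail DNA percent is tail over total
#' (above-background) intensity x 100; tail length is the distance from the
#' measurement origin to the farthest above-background tail bin (0 when no
#' tail bin exists); tail moment is the extent moment,
#' `tail length x tail DNA fraction`. A cell is flagged tailed when its tail
#' DNA percent reaches `tailed_cutoff`.
#'
#' @param cell a [comet_cell()].
#' @param background intensity threshold; bins at or below it are ignored.
#' @param tailed_cutoff tail-DNA percent at or above which the cell counts
#'   as tailed (default 5).
#' @param origin `"edge"` measures tail length from the head boundary,
#'   `"center"` from the head's midpoint — conventions differ across comet
#'   software.
#' @return Data frame row: `tail_length_um`, `tail_dna_pct`, `tail_moment`,
#'   `tailed`.
#' @export
#' @examples
#' cl <- comet_cell(1:20, c(rep(8, 10), rep(2, 10)), head_boundary = 10)
#' comet_cell_metrics(cl)  # 20% tail DNA over a 10-um tail, moment 2
comet_cell_metrics <- function(cell, background = 0, tailed_cutoff = 5,
                               origin = c("edge", "center")) {
  origin <- match.arg(origin)
  if (!is.finite(background) || background < 0) {
    stop("background must be a non-negative number", call. = FALSE)
  }
  keep <- cell$intensity > background
  total <- sum(cell$intensity[keep])
  if (total <= 0) stop("no above-background intensity in cell", call. = FALSE)
  in_tail <- keep & cell$position > cell$head_boundary
  tail_int <- sum(cell$intensity[in_tail])
  tail_dna_pct <- tail_int / total * 100
  origin_pos <- if (origin == "edge") cell$head_boundary else cell$head_boundary / 2
  tail_length <- if (any(in_tail)) max(cell$position[in_tail]) - origin_pos else 0
  data.frame(
    tail_length_um = tail_length,
    tail_dna_pct = tail_dna_pct,
    tail_moment = tail_length * tail_dna_pct / 100,
    tailed = tail_dna_pct >= tailed_cutoff
  )
}

#' Comet endpoints for a whole cell table
#'
#' Applies [comet_cell_metrics()] to every row of a serialized cell table
#' (as produced by [generate_comet_cells()] or read from `comet_cells.csv`).
#'
#' @param cells cell table with columns `individual_id`, `group`, `cell_id`,
#'   `head_boundary_um`, `bin_um`, `profile`.
#' @inheritParams comet_cell_metrics
#' @return Per-cell data frame: ids plus the four endpoints.
#' @export
comet_metrics_table <- function(cells, background = 0, tailed_cutoff = 5,
                                origin = c("edge", "center")) {
  origin <- match.arg(origin)
  profiles <- strsplit(cells$profile, ";", fixed = TRUE)
  met <- lapply(seq_len(nrow(cells)), function(i) {
    int <- as.numeric(profiles[[i]])
    cl <- comet_cell(seq_along(int) * cells$bin_um[i], int,
                     cells$head_boundary_um[i])
    comet_cell_metrics(cl, background = background,
                       tailed_cutoff = tailed_cutoff, origin = origin)
  })
  cbind(cells[, c("individual_id", "group", "cell_id")],
        do.call(rbind, met))
}

#' Group-level comet summary
#'
#' Cell metrics are first averaged within individual — percent tailed cells
#' and the means of tail length, tail DNA percent and tail moment over all
#' scored cells — then summarised per group as mean +/- SE over individuals.
#' An individual contributes only if it has at least one scored cell.
#'
#' @param metrics per-cell metrics from [comet_metrics_table()].
#' @return List with `individuals` (one row per individual) and `groups`
#'   (mean +/- SE of the four endpoints, with `n` individuals).
#' @export
comet_group_summary <- function(metrics) {
  if (!nrow(metrics)) stop("no cells to summarise", call. = FALSE)
  key <- paste(metrics$group, metrics$individual_id, sep = "\r")
  first <- !duplicated(key)
  ind <- data.frame(
    individual_id = metrics$individual_id[first],
    group = metrics$group[first],
    n_cells = as.integer(tapply(rep(1L, nrow(metrics)), key, sum)[key[first]]),
    tailed_pct = as.numeric(tapply(metrics$tailed, key, mean)[key[first]]) * 100,
    tail_length_um = as.numeric(tapply(metrics$tail_length_um, key, mean)[key[first]]),
    tail_dna_pct = as.numeric(tapply(metrics$tail_dna_pct, key, mean)[key[first]]),
    tail_moment = as.numeric(tapply(metrics$tail_moment, key, mean)[key[first]]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  groups <- Reduce(function(a, b) merge(a, b, by = c("group"), sort = FALSE), list(
    group_mean_se(ind$tailed_pct, ind$group, "tailed_pct"),
    group_mean_se(ind$tail_length_um, ind$group, "tail_length_um")[, -2],
    group_mean_se(ind$tail_dna_pct, ind$group, "tail_dna_pct")[, -2],
    group_mean_se(ind$tail_moment, ind$group, "tail_moment")[, -2]
  ))
  list(individuals = ind, groups = groups)
}
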