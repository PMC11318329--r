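#' Default lesion weight table
#'
#' The seven digestive-gland alteration categories and their severity
#' weights, grouped by reaction pattern. Weights run from 1 (minimum
#' biological significance) to 3 (maximum); each category is scored at the
#' levels 0 (absent), 2 (infrequent), 4 (frequent) or 6 (diffuse), so the
#' attributable maximum per category is `weight x max_score`.
#'
#' @param max_score top of the scoring scale (default 6).
#' @return Data frame with columns `category`, `pattern`, `weight` and
#'   attribute `max_score`.
#' @export
#' @examples
#' w <- lesion_weights()
#' sum(w$weight) * attr(w, "max_score")  # 78, the index denominator
lesion_weights <- function(max_score = 6) {
  w <- data.frame(
    category = c("vacuolation", "tubular_atrophy", "tubular_necrosis",
                 "hemocyte_infiltration", "brown_cells", "fibrosis",
                 "intertubular_necrosis"),
    pattern = c("tubular", "tubular", "tubular",
                "intertubular", "intertubular", "intertubular", "intertubular"),
    weight = c(1, 2, 3, 1, 1, 2, 3),
    stringsAsFactors = FALSE
  )
  attr(w, "max_score") <- max_score
  w
}

score_levels <- function(max_score = 6) seq(0, max_score, by = 2)

#' Weighted histopathological condition index
#'
#' For one individual's scores `a_j` over the weighted categories, the index
#' is `sum(w_j * a_j) / sum(w_j * max_score)`; the denominator standardises
#' it to \[0, 1\] so groups are directly comparable. With the default weight
#' table the denominator is 78.
#'
#' @param scores named numeric vector (or one-row data frame) of scores, one
#'   per weight-table category, each in \{0, 2, 4, 6\}.
#' @param weights a [lesion_weights()]-style table.
#' @return The index value in \[0, 1\].
#' @export
#' @examples
#' s <- c(vacuolation = 2, tubular_atrophy = 4, tubular_necrosis = 0,
#'        hemocyte_infiltration = 2, brown_cells = 0, fibrosis = 2,
#'        intertubular_necrosis = 6)
#' condition_index(s)  # 34/78
condition_index <- function(scores, weights = lesion_weights()) {
  if (is.data.frame(scores)) scores <- unlist(scores[1, , drop = TRUE])
  max_score <- attr(weights, "max_score")
  missing <- setdiff(weights$category, names(scores))
  if (length(missing)) {
    stop("missing scores for categories: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  a <- as.numeric(scores[weights$category])
  if (any(!a %in% score_levels(max_score))) {
    stop("scores must lie on the levels ",
         paste(score_levels(max_score), collapse = "/"), call. = FALSE)
  }
  sum(weights$weight * a) / sum(weights$weight * max_score)
}

#' Severity class of a condition index
#'
#' Classes follow the published bands low 0.00-0.30, moderate 0.31-0.60 and
#' high 0.61-1.0; for continuous values the bands are implemented as the
#' half-open partition low \[0, 0.30\], moderate (0.30, 0.60\],
#' high (0.60, 1\], which covers all of \[0, 1\] and preserves the class of
#' every tabulated value.
#'
#' @param ih numeric vector of index values in \[0, 1\].
#' @return Character vector in \{"low", "moderate", "high"\}.
#' @export
classify_index <- function(ih) {
  if (any(!is.finite(ih)) || any(ih < 0) || any(ih > 1)) {
    stop("condition index values must lie in [0, 1]", call. = FALSE)
  }
  ifelse(ih <= 0.30, "low", ifelse(ih <= 0.60, "moderate", "high"))
}

#' Condition index per individual from a lesion-score table
#'
#' @param lesions wide lesion table as written by [generate_lesion_scores()]
#'   (`individual_id`, `group`, one column per category).
#' @param weights a [lesion_weights()] table.
#' @return Data frame `individual_id`, `group`, `Ih`, `class`.
#' @export
condition_index_table <- function(lesions, weights = lesion_weights()) {
  ih <- vapply(seq_len(nrow(lesions)), function(i) {
    condition_index(unlist(lesions[i, weights$category, drop = FALSE]), weights)
  }, numeric(1))
  data.frame(
    individual_id = lesions$individual_id,
    group = lesions$group,
    Ih = ih,
    class = classify_index(ih),
    stringsAsFactors = FALSE
  )
}

#' Group summary of condition indices
#'
#' Arithmetic mean and standard error (`sd/sqrt(n)`) of the per-individual
#' indices within each group, with the group classified by its mean index.
#'
#' @param index_table output of [condition_index_table()].
#' @return Data frame `group`, `n`, `mean_Ih`, `se_Ih`, `class`; groups with
#'   a single individual get `se_Ih = NA` with a warning.
#' @export
group_index_summary <- function(index_table) {
  out <- group_mean_se(index_table$Ih, index_table$group, value_name = "Ih")
  out$class <- classify_index(out$mean_Ih)
  out
}

# shared mean +/- SE summariser keeping group label order of first appearance
group_mean_se <- function(values, groups, value_name = "value") {
  groups <- as.character(groups)
  labels <- unique(groups)
  n <- vapply(labels, function(g) sum(groups == g), integer(1))
  m <- vapply(labels, function(g) mean(values[groups == g]), numeric(1))
  se <- vapply(labels, function(g) {
    v <- values[groups == g]
    if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  }, numeric(1))
  if (anyNA(se)) warning("standard error undefined for single-individual groups")
  out <- data.frame(group = labels, n = n, mean = m, se = se,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[3:4] <- paste0(c("mean_", "se_"), value_name)
  out
}

#' Relative tubule lumen and wall areas
#'
#' Adds per-tubule `rel_lumen_pct = lumen/total x 100` and
#' `rel_wall_pct = wall/total x 100`. Wall area is accepted as measured and
#' cross-checked against `total - lumen`: a relative closure error above
#' `tol` raises a consistency warning rather than being silently forced.
#'
#' @param morphometry data frame with `tubule_area_um2`, `lumen_area_um2`,
#'   `wall_area_um2`.
#' @param tol relative tolerance on `lumen + wall = total` (default 1 percent).
#' @return The input with the two percentage columns appended.
#' @export
relative_tubule_areas <- function(morphometry, tol = 0.01) {
  a <- morphometry$tubule_area_um2
  l <- morphometry$lumen_area_um2
  w <- morphometry$wall_area_um2
  if (any(a <= 0)) stop("tubule area must be positive", call. = FALSE)
  if (any(l < 0) || any(w < 0)) stop("areas must be non-negative", call. = FALSE)
  closure <- abs(l + w - a) / a
  if (any(closure > tol)) {
    warning(sum(closure > tol), " tubule(s) violate lumen + wall = total ",
            "beyond the ", tol * 100, "% tolerance")
  }
  morphometry$rel_lumen_pct <- l / a * 100
  morphometry$rel_wall_pct <- w / a * 100
  morphometry
}

#' Per-individual and per-group morphometry summaries
#'
#' Each individual's value is the average of its tubules (five per animal in
#' the default design); groups are then summarised as mean +/- SE over
#' individuals.
#'
#' @param morphometry data frame as from [generate_morphometry()].
#' @param tol closure tolerance passed to [relative_tubule_areas()].
#' @return List with `individuals` (per-individual means of the two relative
#'   areas) and `groups` (mean +/- SE of each per group).
#' @export
morphometry_summary <- function(morphometry, tol = 0.01) {
  m <- relative_tubule_areas(morphometry, tol = tol)
  key <- paste(m$group, m$individual_id, sep = "\r")
  agg <- function(v) tapply(v, key, mean)
  first <- !duplicated(key)
  ind <- data.frame(
    individual_id = m$individual_id[first],
    group = m$group[first],
    rel_lumen_pct = as.numeric(agg(m$rel_lumen_pct)[key[first]]),
    rel_wall_pct = as.numeric(agg(m$rel_wall_pct)[key[first]]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  lum <- group_mean_se(ind$rel_lumen_pct, ind$group, "rel_lumen_pct")
  wal <- group_mean_se(ind$rel_wall_pct, ind$group, "rel_wall_pct")
  list(individuals = ind, groups = merge(lum, wal[, c(1, 3, 4)], by = "group", sort = FALSE))
}
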