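TIME_GRID <- seq(0, 140, by = 20)

#' Select the study set from a full ncRNA catalog
#'
#' Applies the catalog filter chain: drop translational-machinery records
#' (tRNAs and ribosome-related RNAs) and the tmRNA, then drop ncRNAs that
#' were already characterized in earlier work. Counts are reported at the
#' level of distinct ncRNA identifiers (an ncRNA with several TSS rows is
#' one ncRNA).
#'
#' @param catalog An `ncrna_catalog`; every row must carry an annotation
#'   category.
#' @param characterized_ids Identifiers of previously characterized
#'   ncRNAs to exclude. The default names the two characterized sRNAs of
#'   the *C. crescentus* catalog: the general-stress sRNA (GsrN, the
#'   stationary-phase record) and the carbon-starvation sRNA (CrfA, a
#'   minimal-medium record).
#' @return The surviving catalog rows, with an attribute `filter_counts`
#'   (named integer vector: `input`, `after_machinery`, `final`, distinct
#'   ncRNA ids at each step).
#' @export
select_study_set <- function(catalog,
                             characterized_ids = c("CCNA_R0019",
                                                   "CCNA_R0063")) {
  if (any(is.na(catalog$annotation) | !nzchar(catalog$annotation))) {
    stop("every catalog record needs an annotation category")
  }
  ann <- tolower(catalog$annotation)
  machinery <- grepl("translational machinery|trna|ribosom", ann) &
    !grepl("tmrna", ann)
  tmrna <- grepl("tmrna", ann)
  characterized <- catalog$ccna %in% characterized_ids |
    grepl("characterized", ann)
  step1 <- catalog[!(machinery | tmrna), , drop = FALSE]
  final <- step1[!(step1$ccna %in% characterized_ids) &
                   !grepl("characterized", tolower(step1$annotation)),
                 , drop = FALSE]
  counts <- c(input = length(unique(catalog$ccna)),
              after_machinery = length(unique(step1$ccna)),
              final = length(unique(final$ccna)))
  rownames(final) <- NULL
  attr(final, "filter_counts") <- counts
  final
}

#' Classify a synchrony time course into a cell-cycle phase
#'
#' The classifier is a declared heuristic with three steps. (1) A
#' dynamic-range gate: profiles with `(max + 1) / (min + 1)` below
#' `fold_threshold` or a maximum below `min_peak` are not cell-cycle
#' regulated (`NA`). (2) A U-shape test: if both endpoint values (0 and
#' 140 min) are at least `u_ratio` times the minimum over the 40-100 min
#' core, expression dips mid-cycle and the profile is `G1-G2`. (3)
#' Otherwise the peak time maps to a phase: 0 min (swarmer) is `G1`,
#' 20 min (swarmer-to-stalked transition) is `G1-S`, 40-100 min is `S`
#' and 120-140 min is `G2`.
#'
#' @param values Numeric vector of 8 nonnegative expression values on the
#'   0, 20, ..., 140 min grid.
#' @param fold_threshold Dynamic-range gate; default 4.
#' @param min_peak Minimum peak expression; default 5.
#' @param u_ratio Endpoint-to-core ratio of the U-shape test; default 3.
#' @return One of `"G1"`, `"G1-S"`, `"S"`, `"G2"`, `"G1-G2"`, or
#'   `NA_character_` for a non-cycling profile.
#' @export
classify_phase <- function(values, fold_threshold = 4, min_peak = 5,
                           u_ratio = 3) {
  stopifnot(length(values) == length(TIME_GRID), all(values >= 0))
  if ((max(values) + 1) / (min(values) + 1) < fold_threshold ||
      max(values) < min_peak) {
    return(NA_character_)
  }
  core <- values[TIME_GRID >= 40 & TIME_GRID <= 100]
  if (values[1] >= u_ratio * min(core) &&
      values[length(values)] >= u_ratio * min(core)) {
    return("G1-G2")
  }
  peak_time <- TIME_GRID[which.max(values)]
  if (peak_time == 0) "G1"
  else if (peak_time == 20) "G1-S"
  else if (peak_time <= 100) "S"
  else "G2"
}

#' Classify every time course in a catalog
#'
#' @param catalog An `ncrna_catalog`.
#' @inheritParams classify_phase
#' @return The catalog with a `phase_called` column appended.
#' @export
classify_catalog <- function(catalog, fold_threshold = 4, min_peak = 5,
                             u_ratio = 3) {
  expr <- as.matrix(catalog[CATALOG_TIME_COLS])
  catalog$phase_called <- apply(expr, 1L, classify_phase,
                                fold_threshold = fold_threshold,
                                min_peak = min_peak, u_ratio = u_ratio)
  catalog
}

#' Tally phase labels at TSS or ncRNA level
#'
#' At `tss` level every phase-annotated TSS row counts. At `ncrna` level
#' each distinct identifier with at least one phase-annotated row counts
#' once; if its rows disagree the majority phase wins (warning), ties
#' resolved by the row with the smallest TSS coordinate.
#'
#' @param catalog An `ncrna_catalog` with a `phase` column (parsed or
#'   use `phase_col = "phase_called"` after [classify_catalog()]).
#' @param level `"tss"` or `"ncrna"`.
#' @param phase_col Which column holds the labels; default `"phase"`.
#' @return Named integer vector over the phase levels, with attribute
#'   `n_labelled` (total labelled rows or distinct labelled ncRNAs).
#' @export
count_by_phase <- function(catalog, level = c("tss", "ncrna"),
                           phase_col = "phase") {
  level <- match.arg(level)
  phase <- catalog[[phase_col]]
  if (level == "tss") {
    lab <- phase[!is.na(phase)]
  } else {
    lab <- character(0)
    for (id in unique(catalog$ccna)) {
      rows <- which(catalog$ccna == id & !is.na(phase))
      if (!length(rows)) next
      ph <- phase[rows]
      tab <- table(ph)
      if (length(tab) > 1L) {
        warning(sprintf("conflicting phases for %s: %s", id,
                        paste(names(tab), collapse = ", ")))
        top <- names(tab)[tab == max(tab)]
        if (length(top) > 1L) {
          ord <- rows[order(catalog$tss[rows])]
          ph_pick <- phase[ord][phase[ord] %in% top][1]
        } else {
          ph_pick <- top
        }
      } else {
        ph_pick <- names(tab)
      }
      lab <- c(lab, ph_pick)
    }
  }
  out <- vapply(PHASE_LEVELS, function(p) sum(lab == p), integer(1))
  attr(out, "n_labelled") <- length(lab)
  out
}
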