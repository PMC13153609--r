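#' Construct a chemoproteomics protein table
#'
#' A table of captured proteins with tumor and paracancerous abundances.
#' Fold change is always recomputed as `abundance_t / abundance_p` on
#' construction; rows with zero paracancerous abundance get an infinite
#' fold change and are flagged.
#'
#' @param df data frame with columns `id`, `mw_kda`, `abundance_t`,
#'   `abundance_p`.
#' @return An object of class `protein_table` (a data frame with
#'   recomputed `fold_change` and `fc_infinite` columns).
#' @export
protein_table <- function(df) {
  need <- c("id", "mw_kda", "abundance_t", "abundance_p")
  if (!all(need %in% names(df))) {
    stop("protein table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(df$mw_kda > 0), all(df$abundance_t >= 0),
            all(df$abundance_p >= 0))
  df$fold_change <- ifelse(df$abundance_p == 0, Inf,
                           df$abundance_t / df$abundance_p)
  df$fc_infinite <- df$abundance_p == 0
  class(df) <- c("protein_table", "data.frame")
  df
}

#' Read a protein table from CSV
#'
#' Expects a header with `id, mw_kda, abundance_t, abundance_p`; any
#' `fold_change` column present in the file is discarded and recomputed.
#'
#' @param path CSV file path.
#' @return A [protein_table].
#' @export
read_protein_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$fold_change <- NULL
  protein_table(df)
}

#' Filter candidate signature proteins
#'
#' The capture-proteomics candidate rule: keep rows with fold change
#' strictly greater than `fc_min` and molecular weight inside the closed
#' window `[mw_lo, mw_hi]` kDa.  Row order is preserved; the operation is
#' idempotent.
#'
#' @param table a [protein_table].
#' @param fc_min fold-change threshold, strict (default 2).
#' @param mw_lo,mw_hi mass window in kDa (default 15–100, closed at both
#'   ends).
#' @return The filtered [protein_table].
#' @export
filter_candidates <- function(table, fc_min = 2, mw_lo = 15, mw_hi = 100) {
  stopifnot(inherits(table, "protein_table"), fc_min > 0, mw_lo < mw_hi)
  keep <- table$fold_change > fc_min &
    table$mw_kda >= mw_lo & table$mw_kda <= mw_hi
  table[keep, , drop = FALSE]
}

#' Union / intersection Venn analysis of captured-protein sets
#'
#' Collapses the per-sample captured-protein id sets of the tumor group
#' and the paracancerous group either by union (T-union vs P-union) or by
#' intersection (T-intersection vs P-intersection), then reports the
#' two-set Venn counts.
#'
#' @param tumor_sets list of character vectors of ids (one per tumor
#'   sample).
#' @param para_sets list of character vectors of ids (one per
#'   paracancerous sample).
#' @param mode `"union_vs_union"` or `"intersection_vs_intersection"`.
#' @return List with counts `t_only`, `shared`, `p_only` (summing to the
#'   size of the combined set) and the membership vectors `t_set`,
#'   `p_set`, `t_only_ids`, `shared_ids`, `p_only_ids`.
#' @export
set_analysis <- function(tumor_sets, para_sets,
                         mode = c("union_vs_union",
                                  "intersection_vs_intersection")) {
  mode <- match.arg(mode)
  if (!length(tumor_sets) || !length(para_sets)) {
    stop("each group needs at least one sample", call. = FALSE)
  }
  collapse <- function(sets) {
    sets <- lapply(sets, function(s) unique(as.character(s)))
    if (mode == "union_vs_union") Reduce(union, sets)
    else Reduce(intersect, sets)
  }
  t_set <- collapse(tumor_sets)
  p_set <- collapse(para_sets)
  shared <- intersect(t_set, p_set)
  list(t_only = length(setdiff(t_set, p_set)), shared = length(shared),
       p_only = length(setdiff(p_set, t_set)),
       t_set = t_set, p_set = p_set,
       t_only_ids = setdiff(t_set, p_set), shared_ids = shared,
       p_only_ids = setdiff(p_set, t_set), mode = mode)
}

# Standard atomic masses: average (IUPAC conventional) and monoisotopic.
.atomic_masses <- local({
  avg <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.973762, Cl = 35.45, Br = 79.904, I = 126.90447,
           F = 18.998403, Na = 22.98976928, K = 39.0983, Ca = 40.078,
           Mg = 24.305, Fe = 55.845, Zn = 65.38, Cu = 63.546,
           Mn = 54.938043, Se = 78.971, Si = 28.085)
  mono <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
            O = 15.9949146221, S = 31.97207069, P = 30.97376151,
            Cl = 34.96885271, Br = 78.9183376, I = 126.904473,
            F = 18.99840316, Na = 22.98976928, K = 38.9637064864,
            Ca = 39.962590863, Mg = 23.985041697, Fe = 55.93493633,
            Zn = 63.92914201, Cu = 62.92959772, Mn = 54.93804391,
            Se = 79.9165218, Si = 27.97692653)
  list(average = avg, monoisotopic = mono)
})

#' Parse an elemental formula string
#'
#' @param formula string such as `"C42H48ClN2I"` (element symbols with
#'   optional counts), or a named integer vector which is validated and
#'   returned.
#' @return Named integer vector of atom counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    counts <- formula
  } else {
    stopifnot(is.character(formula), length(formula) == 1L)
    parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)",
                                          formula))[[1]]
    if (!length(parts) || nchar(paste(parts, collapse = "")) !=
          nchar(formula)) {
      stop("cannot parse formula '", formula, "'", call. = FALSE)
    }
    el <- sub("[0-9]*$", "", parts)
    ct <- as.integer(ifelse(grepl("[0-9]+$", parts),
                            sub("^[A-Za-z]+", "", parts), "1"))
    counts <- tapply(ct, el, sum)
  }
  bad <- setdiff(names(counts), names(.atomic_masses$average))
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 1 | counts != round(counts))) {
    stop("atom counts must be positive integers", call. = FALSE)
  }
  stats::setNames(as.integer(counts), names(counts))
}

#' Mass of an elemental formula
#'
#' Sums standard atomic masses for the variable-modification mass of a
#' dye adduct (or any formula).  Additive over formulas by construction.
#'
#' @param formula formula string or named count vector
#'   (see [parse_formula()]).
#' @param mode `"average"` or `"monoisotopic"`.
#' @return Mass in daltons (full precision; round to 4 decimals for
#'   reporting).
#' @examples
#' modification_mass("H2O")            # 18.015
#' modification_mass("C42H49N2")       # 581.87, the dye-cation adduct
#' @export
modification_mass <- function(formula, mode = c("average",
                                                "monoisotopic")) {
  mode <- match.arg(mode)
  counts <- parse_formula(formula)
  sum(.atomic_masses[[mode]][names(counts)] * counts)
}

#' Curated tumor-signature shortlist
#'
#' The six literature-curated signature proteins bundled as a fixture
#' (curation, not computation): CCT5, CPNE1, FUS, HSPA4, ENO1, EIF5A,
#' with their nominal molecular weights.
#'
#' @return Data frame with `gene` and `mw_kda`.
#' @export
curated_signature_proteins <- function() {
  utils::read.csv(system.file("extdata", "curated_signature_proteins.csv",
                              package = "nirmargin"),
                  stringsAsFactors = FALSE)
}
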