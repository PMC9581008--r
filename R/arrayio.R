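#' Column mapping for GenePix results files
#'
#' Names the GPR columns holding the spot identifier, peptide sequence,
#' foreground and background intensities, and quality flag. The defaults
#' target the 635 nm channel of a GenePix Pro export (the channel used for
#' Alexa Fluor 647 imaging of peptide immunoarrays); override them for other
#' dialects.
#'
#' @param id_col,seq_col,fg_col,bg_col,flag_col Column names in the GPR file.
#'   `flag_col` may be absent from the file, in which case all flags are 0.
#' @return A `column_mapping` object (named list).
#' @export
#' @examples
#' column_mapping()
#' column_mapping(fg_col = "F532 Median", bg_col = "B532 Median")
column_mapping <- function(id_col = "ID", seq_col = "Name",
                           fg_col = "F635 Median", bg_col = "B635 Median",
                           flag_col = "Flags") {
  m <- list(id_col = id_col, seq_col = seq_col, fg_col = fg_col,
            bg_col = bg_col, flag_col = flag_col)
  if (anyDuplicated(unlist(m))) {
    abort("All mapped column names must be distinct.", class = "immunosig_format_error")
  }
  structure(m, class = "column_mapping")
}

new_array_sample <- function(spots, sample_id, cohort) {
  if (nrow(spots) < 1L) {
    abort("An array sample must contain at least one spot.",
          class = "immunosig_validation_error")
  }
  bad <- !is.finite(spots$foreground) | !is.finite(spots$background) |
    spots$foreground < 0 | spots$background < 0
  if (any(bad)) {
    abort(sprintf("Foreground/background must be finite and >= 0 (offending spot(s): %s).",
                  paste(head(spots$spot_id[bad], 5L), collapse = ", ")),
          class = "immunosig_validation_error")
  }
  if (any(!nzchar(spots$spot_id))) {
    abort("Spot IDs must be non-empty.", class = "immunosig_validation_error")
  }
  # random-sequence arrays may leave the sequence cell blank; fall back to the ID
  blank <- is.na(spots$sequence) | !nzchar(spots$sequence)
  spots$sequence[blank] <- spots$spot_id[blank]
  structure(spots,
            class = c("array_sample", class(tibble::tibble())),
            sample_id = sample_id,
            cohort = cohort,
            median_background = median(spots$background))
}

#' @export
print.array_sample <- function(x, ...) {
  cat(sprintf("<array_sample> %s (%s), %d spots, median background %.4g RFU\n",
              attr(x, "sample_id"), attr(x, "cohort") %||% "cohort unset",
              nrow(x), attr(x, "median_background")))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

.numeric_or_abort <- function(x, col, first_line, what = "value") {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    abort(sprintf("Non-numeric %s in column '%s' at line %d: '%s'.",
                  what, col, first_line + bad[1] - 1L, x[bad[1]]),
          class = "immunosig_parse_error")
  }
  out
}

#' Read a GenePix results (GPR/ATF) file as one array sample
#'
#' Parses an ATF 1.0 file (GenePix results export): the `ATF` version line, a
#' header-record count line, `"key=value"` header records, a tab-separated
#' column header row, then one row per spot. One file corresponds to one
#' array (one sample).
#'
#' @param path Path to the GPR file.
#' @param mapping A [column_mapping()] naming the ID, sequence, foreground,
#'   background and flag columns.
#' @param exclude_flagged Drop spots whose quality flag is negative (the
#'   GenePix convention for bad spots). The number dropped is reported.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param cohort `"control"`, `"treatment"`, or `NA` to assign later.
#' @return An `array_sample`: a tibble of spots (`spot_id`, `sequence`,
#'   `foreground`, `background`, `flag`, and grid position columns when
#'   present) with the sample id, cohort, and the array-wide median
#'   background as attributes.
#' @export
read_gpr <- function(path, mapping = column_mapping(), exclude_flagged = TRUE,
                     sample_id = tools::file_path_sans_ext(basename(path)),
                     cohort = NA_character_) {
  lines <- readr::read_lines(path)
  if (length(lines) < 4L || !grepl("^ATF", lines[[1]])) {
    abort(sprintf("'%s' is not an ATF file: missing ATF version line.", path),
          class = "immunosig_format_error")
  }
  counts <- suppressWarnings(as.integer(strsplit(lines[[2]], "\t")[[1]]))
  if (length(counts) < 1L || is.na(counts[1])) {
    abort(sprintf("'%s': malformed ATF record-count line.", path),
          class = "immunosig_format_error")
  }
  n_rec <- counts[1]
  header_line <- 3L + n_rec
  if (length(lines) <= header_line) {
    abort(sprintf("'%s': no data rows after ATF header.", path),
          class = "immunosig_format_error")
  }
  tab <- readr::read_tsv(I(lines[header_line:length(lines)]),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  needed <- c(mapping$id_col, mapping$seq_col, mapping$fg_col, mapping$bg_col)
  miss <- setdiff(needed, names(tab))
  if (length(miss)) {
    abort(sprintf("GPR file '%s' is missing mapped column(s): %s.",
                  path, paste(sQuote(miss), collapse = ", ")),
          class = "immunosig_format_error")
  }
  first_data_line <- header_line + 1L
  spots <- tibble::tibble(
    spot_id = tab[[mapping$id_col]],
    sequence = tab[[mapping$seq_col]],
    foreground = .numeric_or_abort(tab[[mapping$fg_col]], mapping$fg_col,
                                   first_data_line, "foreground"),
    background = .numeric_or_abort(tab[[mapping$bg_col]], mapping$bg_col,
                                   first_data_line, "background"),
    flag = if (mapping$flag_col %in% names(tab)) {
      as.integer(.numeric_or_abort(tab[[mapping$flag_col]], mapping$flag_col,
                                   first_data_line, "flag"))
    } else 0L
  )
  for (gc in c("Block", "Row", "Column")) {
    if (gc %in% names(tab)) spots[[tolower(gc)]] <- as.integer(tab[[gc]])
  }
  if (exclude_flagged) {
    n_bad <- sum(spots$flag < 0L)
    if (n_bad > 0L) {
      inform(sprintf("Excluding %d flagged spot(s) (flag < 0) from '%s'.",
                     n_bad, sample_id))
      spots <- spots[spots$flag >= 0L, ]
    }
  }
  new_array_sample(spots, sample_id, cohort)
}

#' Read a four-column spot CSV file as one array sample
#'
#' The file must contain at least four comma-separated columns, in order:
#' spot ID, peptide sequence, foreground intensity, background intensity. A
#' header row is detected automatically (first row whose intensity columns
#' are non-numeric) and skipped.
#'
#' @inheritParams read_gpr
#' @return An `array_sample` (see [read_gpr()]).
#' @export
read_spot_csv <- function(path,
                          sample_id = tools::file_path_sans_ext(basename(path)),
                          cohort = NA_character_) {
  tab <- readr::read_csv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(tab) < 4L) {
    abort(sprintf("Spot CSV '%s' has %d column(s); at least 4 are required (ID, sequence, foreground, background).",
                  path, ncol(tab)),
          class = "immunosig_format_error")
  }
  first_line <- 1L
  head_num <- suppressWarnings(as.numeric(unlist(tab[1, 3:4])))
  if (anyNA(head_num)) {           # header row present
    tab <- tab[-1, , drop = FALSE]
    first_line <- 2L
  }
  if (nrow(tab) == 0L) {
    abort(sprintf("Spot CSV '%s' contains no data rows.", path),
          class = "immunosig_format_error")
  }
  spots <- tibble::tibble(
    spot_id = tab[[1]],
    sequence = tab[[2]],
    foreground = .numeric_or_abort(tab[[3]], "foreground", first_line, "foreground"),
    background = .numeric_or_abort(tab[[4]], "background", first_line, "background"),
    flag = if (ncol(tab) >= 5L)
      as.integer(.numeric_or_abort(tab[[5]], "flag", first_line, "flag")) else 0L
  )
  dup <- unique(spots$spot_id[duplicated(spots$spot_id)])
  if (length(dup)) {
    abort(sprintf("Duplicate spot ID(s) in '%s': %s.",
                  path, paste(head(dup, 10L), collapse = ", ")),
          class = "immunosig_validation_error")
  }
  new_array_sample(spots, sample_id, cohort)
}

#' Read a targeting file for targeted visualization
#'
#' A targeting file maps spot IDs to a pathogen, a source protein, and
#' 1-based inclusive start/end positions of each peptide within that
#' protein. Positional plots (heatmap, line graph, epitope map) require the
#' records to tile a contiguous run of a single protein; strip plots accept
#' an arbitrary collection of peptides.
#'
#' @param path CSV file with header `pathogen,protein,start,end,spot_id`.
#' @param require_contiguous Enforce single-protein, gap-free coverage
#'   (sorted by start, each start at most the previous end + 1).
#' @return A `targeting_table` tibble with those five columns.
#' @export
read_targeting <- function(path, require_contiguous = TRUE) {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  miss <- setdiff(c("pathogen", "protein", "start", "end", "spot_id"), names(tab))
  if (length(miss)) {
    abort(sprintf("Targeting file '%s' is missing column(s): %s.",
                  path, paste(sQuote(miss), collapse = ", ")),
          class = "immunosig_format_error")
  }
  out <- tibble::tibble(
    pathogen = tab$pathogen,
    protein = tab$protein,
    start = as.integer(.numeric_or_abort(tab$start, "start", 2L, "position")),
    end = as.integer(.numeric_or_abort(tab$end, "end", 2L, "position")),
    spot_id = tab$spot_id
  )
  validate_targeting(out, require_contiguous = require_contiguous)
  structure(out, class = c("targeting_table", class(out)))
}

validate_targeting <- function(tt, require_contiguous = TRUE) {
  bad <- tt$start < 1L | tt$start > tt$end
  if (any(bad)) {
    abort(sprintf("Targeting records must satisfy 1 <= start <= end (offending spot(s): %s).",
                  paste(head(tt$spot_id[bad], 5L), collapse = ", ")),
          class = "immunosig_validation_error")
  }
  if (require_contiguous) {
    if (length(unique(tt$protein)) > 1L) {
      abort(sprintf("Contiguous targeting requires a single protein; found: %s.",
                    paste(unique(tt$protein), collapse = ", ")),
            class = "immunosig_validation_error")
    }
    s <- tt[order(tt$start, tt$end), ]
    run_end <- s$end[1]
    for (i in seq_len(nrow(s))[-1]) {
      if (s$start[i] > run_end + 1L) {
        abort(sprintf("Targeting positions are not contiguous: gap at %d..%d.",
                      run_end + 1L, s$start[i] - 1L),
              class = "immunosig_validation_error")
      }
      run_end <- max(run_end, s$end[i])
    }
  }
  invisible(tt)
}

synoptic_stat_cols <- c("control_mean", "control_var", "treatment_mean",
                        "treatment_var", "delta_rfu", "p_raw", "p_adj")

#' Write a synoptic results table to CSV
#'
#' Columns are written in the fixed layout of the synoptic results file:
#' spot ID, peptide sequence, one column per sample (control block then
#' treatment block, each in upload order, headed `cohort:sample_id`),
#' control mean, control variance, treatment mean, treatment variance,
#' delta RFU (treatment mean minus control mean), raw p-value, adjusted
#' p-value. Numeric values round-trip losslessly through
#' [read_synoptic_csv()].
#'
#' @param table A `synoptic_table` from [build_synoptic_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_synoptic_csv <- function(table, path) {
  samples <- attr(table, "samples")
  stopifnot(!is.null(samples))
  out <- table[, c("spot_id", "sequence", samples$sample_id, synoptic_stat_cols)]
  # cohort variance is undefined (NA) for a single-sample cohort; any other
  # missing cell indicates corruption
  may_na <- c("control_var", "treatment_var")
  if (anyNA(out[, setdiff(names(out), may_na)])) {
    abort("Synoptic table contains missing cells; cannot write.",
          class = "immunosig_validation_error")
  }
  names(out) <- c("Spot_ID", "Sequence",
                  paste(samples$cohort, samples$sample_id, sep = ":"),
                  "Control_Mean", "Control_Variance", "Treatment_Mean",
                  "Treatment_Variance", "Delta_RFU", "P_Raw", "P_Adjusted")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a synoptic results CSV back into a synoptic table
#'
#' @param path A CSV written by [write_synoptic_csv()] (or any file in the
#'   same layout).
#' @return A `synoptic_table` tibble.
#' @export
read_synoptic_csv <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    Spot_ID = readr::col_character(), Sequence = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE)
  fixed <- c("Spot_ID", "Sequence", "Control_Mean", "Control_Variance",
             "Treatment_Mean", "Treatment_Variance", "Delta_RFU", "P_Raw",
             "P_Adjusted")
  miss <- setdiff(fixed, names(tab))
  if (length(miss)) {
    abort(sprintf("Synoptic CSV '%s' is missing column(s): %s.",
                  path, paste(sQuote(miss), collapse = ", ")),
          class = "immunosig_format_error")
  }
  sample_cols <- setdiff(names(tab), fixed)
  if (!length(sample_cols) || !all(grepl("^(control|treatment):", sample_cols))) {
    abort(sprintf("Synoptic CSV '%s': per-sample columns must be headed 'control:<id>' or 'treatment:<id>'.",
                  path), class = "immunosig_format_error")
  }
  samples <- tibble::tibble(
    sample_id = sub("^(control|treatment):", "", sample_cols),
    cohort = sub(":.*$", "", sample_cols)
  )
  samples <- samples[order(match(samples$cohort, c("control", "treatment"))), ]
  out <- tibble::tibble(spot_id = tab$Spot_ID, sequence = tab$Sequence)
  for (i in seq_len(nrow(samples))) {
    out[[samples$sample_id[i]]] <-
      tab[[paste(samples$cohort[i], samples$sample_id[i], sep = ":")]]
  }
  out$control_mean <- tab$Control_Mean
  out$control_var <- tab$Control_Variance
  out$treatment_mean <- tab$Treatment_Mean
  out$treatment_var <- tab$Treatment_Variance
  out$delta_rfu <- tab$Delta_RFU
  out$p_raw <- tab$P_Raw
  out$p_adj <- tab$P_Adjusted
  new_synoptic_table(out, samples)
}
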