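# Readers/writers for MAF, GMT and clinical tables. Only the columns the
# analysis needs are kept; everything is plain TSV so artifacts stay diffable.

MAF_REQUIRED <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")

# MAF controlled vocabulary for variant classifications.
MAF_CLASSES <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Splice_Site", "Translation_Start_Site", "Silent", "Intron",
  "3'UTR", "5'UTR", "3'Flank", "5'Flank", "IGR", "RNA", "Targeted_Region"
)

#' Read a mutation annotation format (MAF) file
#'
#' Keeps the three columns used downstream (`Hugo_Symbol`,
#' `Tumor_Sample_Barcode`, `Variant_Classification`); other columns are
#' ignored with a message. Duplicate (sample, gene, classification) records
#' are allowed (multi-hit).
#'
#' @param path Tab-separated MAF file; lines starting with `#` are skipped.
#' @return A `data.frame` with columns `sample_id`, `gene`,
#'   `variant_classification`.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(MAF_REQUIRED, names(df))
  if (length(missing))
    stop("MAF file ", path, " is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), MAF_REQUIRED)
  if (length(extra))
    message("ignoring ", length(extra), " extra MAF column(s): ",
            paste(utils::head(extra, 5L), collapse = ", "))
  bad <- setdiff(unique(df$Variant_Classification), MAF_CLASSES)
  if (length(bad))
    warning("unrecognized variant classification(s): ",
            paste(bad, collapse = ", "))
  data.frame(sample_id = as.character(df$Tumor_Sample_Barcode),
             gene = as.character(df$Hugo_Symbol),
             variant_classification = as.character(df$Variant_Classification),
             stringsAsFactors = FALSE)
}

#' Write a mutation table back to MAF
#' @param mut Mutation table as returned by [read_maf].
#' @param path Output path.
#' @export
write_maf <- function(mut, path) {
  df <- data.frame(Hugo_Symbol = mut$gene,
                   Tumor_Sample_Barcode = mut$sample_id,
                   Variant_Classification = mut$variant_classification,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`. Members are
#' de-duplicated within a set; empty sets are an error.
#'
#' @param path GMT file path.
#' @return Named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short))
    stop("GMT line(s) with no members: ",
         paste(vapply(parts[short], `[`, "", 1L), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  attr(sets, "description") <- stats::setNames(vapply(parts, `[`, "", 2L),
                                               names(sets))
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to set names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "description")
  if (is.null(descriptions)) descriptions <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table
#'
#' Expects per-sample rows with a sample id, overall-survival time and event
#' indicator; any other columns are carried along as covariates. Event coding
#' is mapped through `event_map` (e.g. `c(Dead = 1, Alive = 0)`); numeric 0/1
#' passes through. The survival time unit is recorded as metadata and never
#' converted implicitly.
#'
#' @param path TSV path.
#' @param sample_col,time_col,event_col Column names in the file.
#' @param event_map Named vector mapping event labels to 0/1.
#' @param time_unit Unit label recorded in the `time_unit` attribute.
#' @return `data.frame` with columns `sample_id`, `os_time`, `os_event`, plus
#'   covariates.
#' @export
read_clinical <- function(path, sample_col = "sample_id",
                          time_col = "os_time", event_col = "os_event",
                          event_map = c("1" = 1, "0" = 0,
                                        "Dead" = 1, "Alive" = 0),
                          time_unit = "days") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(c(sample_col, time_col, event_col), names(df))
  if (length(missing))
    stop("clinical table missing column(s): ", paste(missing, collapse = ", "))
  out <- df
  names(out)[match(c(sample_col, time_col, event_col), names(df))] <-
    c("sample_id", "os_time", "os_event")
  out$sample_id <- as.character(out$sample_id)
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample id(s) in clinical table")
  ev <- as.character(out$os_event)
  unknown <- setdiff(unique(ev), names(event_map))
  if (length(unknown))
    stop("unmapped os_event value(s): ", paste(unknown, collapse = ", "))
  out$os_event <- as.numeric(event_map[ev])
  out$os_time <- as.numeric(out$os_time)
  if (any(is.na(out$os_time)) || any(out$os_time < 0))
    stop("os_time must be non-negative and numeric")
  attr(out, "time_unit") <- time_unit
  out
}

#' Write a clinical table as TSV
#' @param clinical Clinical `data.frame`.
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
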