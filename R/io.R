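## Readers, writers and validation for the formats the pipeline touches:
## expression TSV/GCT, GMT gene sets, clinical TSV, MAF-lite TSV, SEG TSV.

#' Construct a validated expression matrix
#'
#' An `ExpressionMatrix` is a numeric genes x samples matrix (log2-scale
#' abundance) with a cohort (cancer-type) label per sample.
#'
#' @param values Numeric matrix, rows = genes, columns = samples, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param cohort_of Named character vector mapping every sample id to its
#'   cohort label. Unnamed vectors of length `ncol(values)` are accepted and
#'   matched positionally.
#' @return An object of class `ExpressionMatrix` (a list with `values` and
#'   `cohort_of`).
#' @export
expression_matrix <- function(values, cohort_of) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (nrow(values) < 2L || ncol(values) < 1L)
    stop("need at least 2 genes and 1 sample")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (!all(is.finite(values)))
    stop("expression values must be finite (missing cells are rejected, not imputed)")
  cohort_of <- as.character_named(cohort_of, colnames(values), "cohort_of")
  structure(list(values = values, cohort_of = cohort_of),
            class = "ExpressionMatrix")
}

## accept positional or named maps keyed by sample id
as.character_named <- function(x, ids, what) {
  nm <- names(x)
  x <- vapply(x, as.character, character(1), USE.NAMES = FALSE)
  names(x) <- nm
  if (is.null(names(x))) {
    if (length(x) != length(ids))
      stop(what, " must have one entry per sample")
    names(x) <- ids
  }
  if (!all(ids %in% names(x)))
    stop(what, " missing labels for: ",
         paste(utils::head(setdiff(ids, names(x)), 5L), collapse = ", "))
  x[ids]
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples, %d cohort(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$cohort_of))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (unique genes per set).
#' @param description Optional named character vector of free-text
#'   descriptions; defaults to the set names.
#' @return A `GeneSetCollection` object.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (length(sets) == 0L) stop("empty collection")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all sets must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    if (length(g) == 0L) stop("empty gene set")
    if (anyDuplicated(g)) {
      warning("duplicate genes within a set de-duplicated (first occurrence kept)")
      g <- g[!duplicated(g)]
    }
    g
  })
  if (is.null(description)) description <- stats::setNames(names(sets), names(sets))
  structure(list(sets = sets, description = description[names(sets)]),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d set(s)\n", length(x$sets)))
  for (nm in utils::head(names(x$sets), 10L))
    cat(sprintf("  %s (%d genes)\n", nm, length(x$sets[[nm]])))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Read an expression matrix from TSV or GCT
#'
#' TSV dialect: first column gene id, header row of sample ids. GCT v1.2:
#' two header lines (`#1.2`, then `n_genes TAB n_samples`) followed by
#' `Name`, `Description` and sample columns.
#'
#' @param path File path.
#' @param format `"tsv"`, `"gct"`, or `"auto"` (by file extension).
#' @param cohort_of Optional named cohort map; defaults to a single cohort
#'   `"ALL"` (cohorts usually come from the clinical table).
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to raw counts.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct"),
                            cohort_of = NULL, log2_transform = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  if (format == "gct") {
    hdr <- readLines(path, n = 2L)
    if (length(hdr) < 2L || !startsWith(hdr[1L], "#1.2"))
      stop("not a GCT v1.2 file: ", path)
    df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                            colClasses = "character")
    dims <- as.integer(strsplit(hdr[2L], "\t")[[1L]][1:2])
    if (!is.na(dims[1L]) && nrow(df) != dims[1L])
      stop("GCT header declares ", dims[1L], " genes, found ", nrow(df))
    gene_ids <- df[[1L]]
    body <- df[, -(1:2), drop = FALSE]   # drop Name, Description
  } else {
    df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
    gene_ids <- df[[1L]]
    body <- df[, -1L, drop = FALSE]
  }
  if (anyDuplicated(gene_ids))
    stop("duplicate gene rows in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(gene_ids, colnames(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at gene ", gene_ids[bad[1L]],
         ", sample ", colnames(body)[bad[2L]])
  }
  if (log2_transform) vals <- log2(vals + 1)
  if (is.null(cohort_of))
    cohort_of <- stats::setNames(rep("ALL", ncol(vals)), colnames(vals))
  expression_matrix(vals, cohort_of)
}

#' Write an expression matrix as TSV (or GCT)
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @param format `"tsv"` or `"gct"`.
#' @export
write_expression <- function(em, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE)
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(em$values), ncol(em$values), sep = "\t")), con)
    df <- data.frame(Name = rownames(em$values),
                     Description = rownames(em$values),
                     em$values, check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line is `name TAB description TAB gene1 TAB gene2 ...`. Duplicate
#' genes within a line are dropped (first kept) with a warning; duplicate
#' set names are an error.
#'
#' @param path File path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    stop("duplicate set name in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  desc <- stats::setNames(vapply(fields, `[[`, character(1), 2L), nms)
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), nms)
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection to GMT
#' @param gsc A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$description[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table
#'
#' Required columns: `sample_id`, `os_time` (days, >= 0), `os_event`
#' (1 = death observed, 0 = censored), `cohort`. Optional: `stage`.
#'
#' @param path File path.
#' @return A `data.frame` of class `ClinicalTable`.
#' @export
read_clinical <- function(path) {
  df <- read_tsv_required(path, c("sample_id", "os_time", "os_event", "cohort"))
  df$sample_id <- trimws(df$sample_id)
  df$os_time <- as_numeric_col(df$os_time, "os_time", path)
  df$os_event <- as_numeric_col(df$os_event, "os_event", path)
  if (!"stage" %in% names(df)) df$stage <- NA_character_
  validate_clinical(df)
}

validate_clinical <- function(df) {
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  bad <- which(df$os_time < 0)
  if (length(bad)) stop("negative os_time at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!df$os_event %in% c(0, 1))
  if (length(bad)) stop("os_event outside {0,1} at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' Default nonsynonymous variant classes used for TMB
#' @export
NONSYN_CLASSES <- c("Missense_Mutation", "Nonsense_Mutation",
                    "Frame_Shift_Del", "Frame_Shift_Ins", "Splice_Site",
                    "In_Frame_Del", "In_Frame_Ins", "Nonstop_Mutation")

MAF_VOCABULARY <- c(NONSYN_CLASSES,
                    "Silent", "Intron", "3'UTR", "5'UTR", "RNA",
                    "Translation_Start_Site", "IGR", "5'Flank", "3'Flank")

#' Read a MAF-lite mutation table
#'
#' Required columns: `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification`. Records are tagged nonsynonymous according to
#' [NONSYN_CLASSES].
#'
#' @param path File path.
#' @return A `data.frame` of class `MutationTable` with columns `sample_id`,
#'   `gene_id`, `variant_classification`, `nonsynonymous`.
#' @export
read_maf_lite <- function(path) {
  df <- read_tsv_required(path, c("Tumor_Sample_Barcode", "Hugo_Symbol",
                                  "Variant_Classification"))
  out <- data.frame(sample_id = trimws(df$Tumor_Sample_Barcode),
                    gene_id = trimws(df$Hugo_Symbol),
                    variant_classification = df$Variant_Classification,
                    stringsAsFactors = FALSE)
  validate_mutations(out)
}

validate_mutations <- function(df) {
  bad <- which(!nzchar(df$sample_id) | !nzchar(df$gene_id))
  if (length(bad)) stop("empty sample or gene id at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  unknown <- setdiff(unique(df$variant_classification), MAF_VOCABULARY)
  if (length(unknown))
    stop("variant_classification outside declared vocabulary: ",
         paste(unknown, collapse = ", "))
  df$nonsynonymous <- df$variant_classification %in% NONSYN_CLASSES
  class(df) <- c("MutationTable", "data.frame")
  df
}

#' Read a SEG copy-number segment table
#'
#' Required columns: `Sample`, `Chromosome`, `Start`, `End`, `Seg.Mean`.
#' Coordinates are 1-based inclusive; per sample, segments on a chromosome
#' must not overlap.
#'
#' @param path File path.
#' @return A `data.frame` of class `CNVSegmentTable` with columns
#'   `sample_id`, `chromosome`, `start`, `end`, `seg_mean`.
#' @export
read_seg <- function(path) {
  df <- read_tsv_required(path, c("Sample", "Chromosome", "Start", "End",
                                  "Seg.Mean"))
  out <- data.frame(sample_id = trimws(df$Sample),
                    chromosome = as.character(df$Chromosome),
                    start = as_numeric_col(df$Start, "Start", path),
                    end = as_numeric_col(df$End, "End", path),
                    seg_mean = as_numeric_col(df$Seg.Mean, "Seg.Mean", path),
                    stringsAsFactors = FALSE)
  validate_seg(out)
}

validate_seg <- function(df) {
  bad <- which(df$start >= df$end)
  if (length(bad)) stop("segment with Start >= End at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  if (!all(is.finite(df$seg_mean))) stop("non-finite seg_mean")
  # overlap check per sample x chromosome
  key <- split(seq_len(nrow(df)), paste(df$sample_id, df$chromosome, sep = "\r"))
  for (idx in key) {
    if (length(idx) < 2L) next
    o <- idx[order(df$start[idx])]
    if (any(df$start[o][-1L] <= df$end[o][-length(o)]))  # 1-based inclusive
      stop("overlapping segments for sample ", df$sample_id[o[1L]],
           " chromosome ", df$chromosome[o[1L]])
  }
  class(df) <- c("CNVSegmentTable", "data.frame")
  df
}

## shared TSV helpers ------------------------------------------------------

read_tsv_required <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  df
}

as_numeric_col <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad))
    stop("unparsable numeric in column ", col, " of ", path,
         " at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  out
}

#' Write a data.frame as TSV (no quoting, no row names)
#' @param df A data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
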