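#' Read a genes x samples expression TSV
#'
#' Tab-separated, first column gene symbol, header row of sample identifiers,
#' log-scale normalized values. Duplicated identifiers, empty cells and
#' non-numeric cells are format errors naming the offending row/column.
#'
#' @param path path to the TSV file.
#' @return an \code{\linkS4class{ExpressionMatrix}}, load order preserved.
#' @export
readExpressionTsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene column and >= 1 sample")
  genes <- trimws(df[[1L]])
  samples <- trimws(colnames(df)[-1L])
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene id: %s", genes[duplicated(genes)][1L]))
  if (anyDuplicated(samples))
    stop(sprintf("duplicate sample id: %s", samples[duplicated(samples)][1L]))
  vals <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    raw <- trimws(df[[j + 1L]])
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | raw == "")
    if (length(bad))
      stop(sprintf("non-numeric or missing value at row %d (gene %s), column %s",
                   bad[1L], genes[bad[1L]], samples[j]))
    vals[, j] <- num
  }
  if (!all(is.finite(vals))) {
    ij <- which(!is.finite(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at gene %s, sample %s",
                 genes[ij[1L]], samples[ij[2L]]))
  }
  ExpressionMatrix(vals)
}

#' Write an ExpressionMatrix to TSV
#'
#' Inverse of \code{\link{readExpressionTsv}}; round-trips content exactly
#' (up to full-precision decimal formatting).
#'
#' @param x an ExpressionMatrix.
#' @param path output path.
#' @param geneColumn header for the gene column.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTsv <- function(x, path, geneColumn = "gene") {
  stopifnot(is(x, "ExpressionMatrix"))
  df <- data.frame(gene = geneIds(x),
                   format(exprValues(x), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(geneColumn, sampleIds(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then one or more genes, tab-separated.
#' Duplicate genes within a line are deduplicated with a warning; a duplicate
#' set name or a line with zero genes is a format error.
#'
#' @param path path to a GMT file.
#' @return a \code{\linkS4class{SignatureCollection}}.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1L]])
    if (length(f) < 3L || !any(nzchar(f[-(1:2)])))
      stop(sprintf("GMT line %d ('%s') has zero genes", i, f[1L]))
    nm <- f[1L]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': duplicate genes deduplicated (%s)",
                      nm, paste(unique(genes[duplicated(genes)]),
                                collapse = ", ")))
      genes <- unique(genes)
    }
    if (nm %in% names(sets))
      stop(sprintf("duplicate gene-set name: %s", nm))
    sets[[nm]] <- GeneSet(nm, genes)
  }
  SignatureCollection(sets)
}

#' Write a SignatureCollection to GMT
#'
#' @param x a SignatureCollection.
#' @param path output path.
#' @param description description field written for every set.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(x, path, description = "na") {
  stopifnot(is(x, "SignatureCollection"))
  lines <- vapply(geneSets(x), function(s)
    paste(c(setName(s), description, geneMembers(s)), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and validate a clinical annotation table
#'
#' Delimited file with required columns \code{sample_id}, \code{egfr_status}
#' (\code{mutant}/\code{wild-type}, case-insensitive; \code{wt} accepted),
#' \code{os_time} (months, >= 0) and \code{os_event} (0/1). Optional columns
#' (\code{treatment}, \code{response}, \code{statin_use}) pass through.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field separator; \code{"\t"} by default, use \code{","} for CSV.
#' @return a validated data.frame keyed by \code{sample_id}.
#' @export
readClinicalTable <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  validateClinicalTable(df)
}

#' Validate an in-memory clinical table
#'
#' @param df data.frame with the columns of \code{\link{readClinicalTable}}.
#' @return the canonicalized data.frame.
#' @export
validateClinicalTable <- function(df) {
  required <- c("sample_id", "egfr_status", "os_time", "os_event")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  df$sample_id <- trimws(as.character(df$sample_id))
  if (anyDuplicated(df$sample_id))
    stop(sprintf("duplicate sample id: %s",
                 df$sample_id[duplicated(df$sample_id)][1L]))
  st <- tolower(trimws(as.character(df$egfr_status)))
  st[st %in% c("wt", "wild-type", "wildtype", "wild type")] <- "wild-type"
  st[st %in% c("mut", "mutant", "mutated")] <- "mutant"
  bad <- setdiff(unique(st), c("wild-type", "mutant"))
  if (length(bad))
    stop(sprintf("unrecognized egfr_status value: %s", bad[1L]))
  df$egfr_status <- st
  df$os_time <- as.numeric(df$os_time)
  df$os_event <- as.numeric(df$os_event)
  if (any(!is.finite(df$os_time)) || any(df$os_time < 0))
    stop("os_time must be finite and >= 0")
  if (!all(df$os_event %in% c(0, 1)))
    stop("os_event must be 0 or 1")
  df
}

#' Read a study-level hazard-ratio table for meta-analysis
#'
#' CSV with one row per study. Either \code{log_hr} and \code{se} columns, or
#' \code{hr}, \code{ci_lower}, \code{ci_upper} which are converted via
#' log_hr = ln(hr), se = (ln(ci_upper) - ln(ci_lower)) / (2 * 1.959964),
#' the two-sided 95\% normal quantile. Optional columns: \code{n} (enrollment),
#' \code{subgroup}.
#'
#' @param path path to the CSV.
#' @return data.frame with columns \code{study_id}, \code{log_hr}, \code{se},
#'   plus \code{n}/\code{subgroup} when present.
#' @export
readMetaTable <- function(path) {
  df <- read.delim(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  if (!"study_id" %in% colnames(df)) stop("missing required column: study_id")
  df$study_id <- as.character(df$study_id)
  if (all(c("log_hr", "se") %in% colnames(df))) {
    out <- data.frame(study_id = df$study_id,
                      log_hr = as.numeric(df$log_hr),
                      se = as.numeric(df$se), stringsAsFactors = FALSE)
  } else if (all(c("hr", "ci_lower", "ci_upper") %in% colnames(df))) {
    conv <- hrCiToLogHR(as.numeric(df$hr), as.numeric(df$ci_lower),
                        as.numeric(df$ci_upper))
    out <- data.frame(study_id = df$study_id, log_hr = conv$log_hr,
                      se = conv$se, stringsAsFactors = FALSE)
  } else {
    stop("need either (log_hr, se) or (hr, ci_lower, ci_upper) columns")
  }
  if (any(!is.finite(out$log_hr)) || any(!is.finite(out$se)))
    stop("non-finite effect or standard error")
  if (any(out$se <= 0)) stop("se must be > 0 for every study")
  if ("n" %in% colnames(df)) {
    out$n <- as.integer(df$n)
    if (any(is.na(out$n)) || any(out$n < 1)) stop("n must be a positive integer")
  }
  if ("subgroup" %in% colnames(df)) out$subgroup <- as.character(df$subgroup)
  out
}

# two-sided 95% normal quantile, fixed so that conversions are reproducible
.Z95 <- 1.959964

#' Convert HR with 95\% CI to log-HR and standard error
#'
#' @param hr hazard ratio(s), > 0.
#' @param ci_lower,ci_upper 95\% CI bounds, > 0, lower <= upper; an HR outside
#'   its own CI raises a warning, a degenerate CI (zero width) an error.
#' @return list with \code{log_hr} and \code{se}.
#' @export
hrCiToLogHR <- function(hr, ci_lower, ci_upper) {
  if (any(hr <= 0) || any(ci_lower <= 0) || any(ci_upper <= 0))
    stop("hr and CI bounds must be positive")
  if (any(ci_lower > ci_upper)) stop("ci_lower exceeds ci_upper")
  if (any(hr < ci_lower | hr > ci_upper))
    warning("HR outside its own confidence interval")
  se <- (log(ci_upper) - log(ci_lower)) / (2 * .Z95)
  if (any(se <= 0)) stop("degenerate confidence interval: se must be > 0")
  list(log_hr = log(hr), se = se)
}

#' Reconstruct an HR 95\% CI from log-HR and SE
#'
#' Inverse of \code{\link{hrCiToLogHR}} under the same normal quantile.
#'
#' @param log_hr log hazard ratio.
#' @param se standard error, > 0.
#' @return list with \code{hr}, \code{ci_lower}, \code{ci_upper}.
#' @export
logHRToHrCi <- function(log_hr, se) {
  if (any(se <= 0)) stop("se must be > 0")
  list(hr = exp(log_hr), ci_lower = exp(log_hr - .Z95 * se),
       ci_upper = exp(log_hr + .Z95 * se))
}
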