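#' Construct and validate a CNV call table
#'
#' A call table is a plain `data.frame` with one row per putative CNV call and
#' columns `sample_id`, `chrom`, `start`, `end`, `copy_state`, `n_markers` and
#' optionally `source`. Coordinates are 1-based inclusive; the length of a call
#' is `end - start + 1`. Copy states above 3 are retained as read; all
#' classifications collapse them to the `{0, 1, 3+}` set.
#'
#' @param sample_id,chrom,start,end,copy_state,n_markers,source Column vectors
#'   (recycled where scalar).
#' @return A validated `data.frame` of calls, chromosome names normalized.
#' @export
cnv_calls <- function(sample_id, chrom, start, end, copy_state,
                      n_markers = NA_integer_, source = NA_character_) {
  n <- max(length(sample_id), length(chrom), length(start), length(end),
           length(copy_state))
  df <- data.frame(
    sample_id = rep_len(as.character(sample_id), n),
    chrom = if (n) normalize_chrom(rep_len(chrom, n)) else character(),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    copy_state = rep_len(as.integer(copy_state), n),
    n_markers = rep_len(as.integer(n_markers), n),
    source = rep_len(as.character(source), n),
    stringsAsFactors = FALSE
  )
  validate_calls(df)
}

validate_calls <- function(df) {
  req <- c("sample_id", "chrom", "start", "end", "copy_state")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("call table missing columns: ", paste(miss, collapse = ", "))
  if (!"n_markers" %in% names(df)) df$n_markers <- NA_integer_
  if (!"source" %in% names(df)) df$source <- NA_character_
  bad <- which(df$start > df$end)
  if (length(bad))
    stop("invalid call interval (start > end) at row ", bad[1])
  if (any(df$copy_state < 0, na.rm = TRUE)) stop("copy_state must be >= 0")
  df
}

#' Length of call intervals in bp
#'
#' @param calls A call table (or any data.frame with `start`/`end`).
#' @return Numeric vector, `end - start + 1`.
#' @export
cnv_length <- function(calls) calls$end - calls$start + 1

#' Read CNV calls from file
#'
#' Supports three dialects:
#' \describe{
#'   \item{`penncnv_rawcnv`}{PennCNV `rawcnv` lines, e.g.
#'     `chr1:1000-2000  numsnp=12 length=1,001 state2,cn=1 sample1 ...`.}
#'   \item{`tsv`}{Tab-separated with header columns as in [cnv_calls()].}
#'   \item{`bed`}{BED with columns chrom, start, end, name (= sample id),
#'     score (= copy state) and optionally a 6th marker-count column. BED's
#'     0-based half-open coordinates are converted to 1-based inclusive.}
#' }
#'
#' @param path File path.
#' @param dialect One of `"penncnv_rawcnv"`, `"tsv"`, `"bed"`.
#' @param genome Optional [genome_def()]; when given, chromosomes not in the
#'   genome raise an error.
#' @return A call table as in [cnv_calls()].
#' @export
read_cnv_calls <- function(path, dialect = c("tsv", "penncnv_rawcnv", "bed"),
                           genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  calls <- switch(dialect,
    tsv = read_calls_tsv(path),
    penncnv_rawcnv = read_calls_rawcnv(path),
    bed = read_calls_bed(path)
  )
  if (nrow(calls) == 0) warning("no CNV calls read from ", path)
  if (!is.null(genome)) {
    unknown <- setdiff(unique(calls$chrom), names(genome$lengths))
    if (length(unknown))
      stop("unknown chromosome in ", path, ": ", paste(unknown, collapse = ", "))
  }
  validate_calls(calls)
}

read_calls_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character"))
  df$chrom <- normalize_chrom(df$chrom)
  df
}

read_calls_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines))
    return(cnv_calls(character(), character(), numeric(), numeric(), integer())[0, ])
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], " in ", path)
  get <- function(i, default = NA) vapply(parts, function(p)
    if (length(p) >= i) p[i] else as.character(default), character(1))
  start0 <- suppressWarnings(as.numeric(get(2)))
  end0 <- suppressWarnings(as.numeric(get(3)))
  if (any(is.na(start0) | is.na(end0)))
    stop("malformed BED line ", which(is.na(start0) | is.na(end0))[1], " in ", path)
  cnv_calls(
    sample_id = get(4, "unknown"),
    chrom = get(1),
    start = start0 + 1,   # 0-based half-open -> 1-based inclusive
    end = end0,
    copy_state = suppressWarnings(as.integer(get(5, NA))),
    n_markers = suppressWarnings(as.integer(get(6, NA))),
    source = basename(path)
  )
}

read_calls_rawcnv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(cnv_calls(character(), character(), numeric(), numeric(), integer())[0, ])
  loc <- regmatches(lines, regexpr("^\\S+:[0-9,]+-[0-9,]+", lines))
  if (length(loc) != length(lines))
    stop("malformed PennCNV line ",
         which(!grepl("^\\S+:[0-9,]+-[0-9,]+", lines))[1], " in ", path)
  chrom <- sub(":.*$", "", loc)
  start <- as.numeric(gsub(",", "", sub("^.*:([0-9,]+)-.*$", "\\1", loc)))
  end <- as.numeric(gsub(",", "", sub("^.*-([0-9,]+)$", "\\1", loc)))
  grab_num <- function(key) {
    m <- regmatches(lines, regexpr(paste0(key, "=[0-9,]+"), lines))
    has <- grepl(paste0(key, "=[0-9,]+"), lines)
    out <- rep(NA_real_, length(lines))
    out[has] <- as.numeric(gsub(",", "", sub(paste0(key, "="), "", m, fixed = TRUE)))
    out
  }
  cn <- grab_num("cn")
  if (anyNA(cn)) stop("malformed PennCNV line ", which(is.na(cn))[1],
                      " in ", path, " (missing cn=)")
  numsnp <- grab_num("numsnp")
  # sample id: first whitespace token after the state/cn field
  rest <- sub("^.*cn=[0-9]+\\s+", "", lines)
  sample_id <- vapply(strsplit(trimws(rest), "\\s+"), `[`, character(1), 1)
  sample_id <- sub("\\.(cel|txt)$", "", basename(sample_id), ignore.case = TRUE)
  cnv_calls(sample_id, chrom, start, end, as.integer(cn),
            n_markers = as.integer(numsnp), source = basename(path))
}

#' Write intervals as BED (0-based half-open)
#'
#' Inverse of the BED reader: 1-based inclusive internal coordinates are
#' converted so that `read_cnv_calls(write_bed(x), "bed")` round-trips.
#'
#' @param intervals Data frame with `chrom`, `start`, `end` and optionally
#'   `sample_id`/`name`, `copy_state`/`score`, `n_markers`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  if (any(intervals$start > intervals$end)) stop("invalid interval")
  name <- if ("sample_id" %in% names(intervals)) intervals$sample_id
          else if ("name" %in% names(intervals)) intervals$name else "."
  score <- if ("copy_state" %in% names(intervals)) intervals$copy_state
           else if ("score" %in% names(intervals)) intervals$score else "."
  df <- data.frame(chrom = intervals$chrom,
                   start = format(intervals$start - 1, scientific = FALSE, trim = TRUE),
                   end = format(intervals$end, scientific = FALSE, trim = TRUE),
                   name = name, score = score)
  if ("n_markers" %in% names(intervals)) df$n_markers <- intervals$n_markers
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED feature track
#'
#' @param path BED file (0-based half-open; converted to 1-based inclusive).
#' @param name Track name (defaults to file name without extension).
#' @return A `feature_track`: list with `name` and `intervals` data.frame.
#' @export
read_feature_track <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.bed$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) {
    iv <- data.frame(chrom = character(), start = numeric(), end = numeric())
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    iv <- data.frame(
      chrom = normalize_chrom(vapply(parts, `[`, character(1), 1)),
      start = as.numeric(vapply(parts, `[`, character(1), 2)) + 1,
      end = as.numeric(vapply(parts, `[`, character(1), 3))
    )
  }
  feature_track(name, iv)
}

#' @rdname read_feature_track
#' @param intervals Data frame with `chrom`, `start`, `end` (1-based inclusive).
#' @export
feature_track <- function(name, intervals) {
  if (nrow(intervals) && any(intervals$start > intervals$end))
    stop("invalid feature interval (start > end)")
  intervals$chrom <- normalize_chrom(intervals$chrom)
  structure(list(name = name, intervals = intervals), class = "feature_track")
}

#' Read / write the probe annotation table
#'
#' Tab-separated with header columns `id`, `chrom`, `pos`, `type`
#' (`SNP`/`IGP`) and optionally `sequence` (25-mer). Probes are returned
#' sorted by chromosome and position; when sequences are present, probes whose
#' sequence occurs more than once are flagged `duplicate_sequence`.
#'
#' @param path File path.
#' @return Data frame of probes sorted by (chrom, pos) with logical flag
#'   columns `flag_restriction_site`, `flag_overlaps_other`,
#'   `flag_duplicate_sequence` (all initialized where computable).
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(id = "character"))
  req <- c("id", "chrom", "pos", "type")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("probe annotation missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicate probe id: ", df$id[duplicated(df$id)][1])
  probe_table(df)
}

#' @rdname read_probe_annotation
#' @param df Data frame with at least `id`, `chrom`, `pos`, `type`.
#' @export
probe_table <- function(df) {
  df$chrom <- normalize_chrom(df$chrom)
  df$pos <- as.numeric(df$pos)
  if (!all(df$type %in% c("SNP", "IGP")))
    stop("probe type must be 'SNP' or 'IGP'")
  if (!"sequence" %in% names(df)) df$sequence <- NA_character_
  has_seq <- !is.na(df$sequence)
  if (any(has_seq) && any(nchar(df$sequence[has_seq]) != 25))
    stop("probe sequences must be 25 bp")
  df <- df[order(df$chrom, df$pos, df$id), , drop = FALSE]
  rownames(df) <- NULL
  df$flag_duplicate_sequence <- FALSE
  if (any(has_seq)) {
    tab <- table(df$sequence[!is.na(df$sequence)])
    dup <- names(tab)[tab > 1]
    df$flag_duplicate_sequence <- !is.na(df$sequence) & df$sequence %in% dup
  }
  if (!"flag_restriction_site" %in% names(df)) df$flag_restriction_site <- NA
  if (!"flag_overlaps_other" %in% names(df)) df$flag_overlaps_other <- NA
  df
}

#' Read / write a sample metadata table
#'
#' Columns: `sample_id`, `classification` (one of classical, wild_derived,
#' wild_caught, BXD, CC, F1, consomic, congenic), optional `subspecies`
#' (domesticus / musculus / castaneus), `sex` (M/F), `lrr_sd`, `baf_drift`.
#'
#' @param path File path.
#' @return Data frame of sample metadata.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character"))
  req <- c("sample_id", "classification", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample metadata missing columns: ",
                         paste(miss, collapse = ", "))
  ok <- c("classical", "wild_derived", "wild_caught", "BXD", "CC", "F1",
          "consomic", "congenic")
  bad <- setdiff(unique(df$classification), ok)
  if (length(bad)) stop("unknown classification: ", paste(bad, collapse = ", "))
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (any(df$lrr_sd < 0, na.rm = TRUE)) stop("lrr_sd must be >= 0")
  df
}

#' Read / write a genotype matrix
#'
#' Probe-by-sample matrix of genotype calls `AA`/`AB`/`BB`/`NoCall`, stored as
#' TSV with probe ids in the first column and sample ids as header.
#'
#' @param path File path.
#' @param probes Optional probe table; when given, every genotype row id must
#'   exist among the SNP probes.
#' @return Character matrix with probe-id rownames and sample-id colnames.
#' @export
read_genotype_matrix <- function(path, probes = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  bad <- !m %in% c("AA", "AB", "BB", "NoCall")
  if (any(bad)) stop("invalid genotype value: ", unique(m[bad])[1])
  if (!is.null(probes)) {
    snp_ids <- probes$id[probes$type == "SNP"]
    unknown <- setdiff(rownames(m), snp_ids)
    if (length(unknown))
      stop("genotype probe not in annotation: ", unknown[1])
  }
  m
}

#' @rdname read_genotype_matrix
#' @param m Genotype matrix as returned by `read_genotype_matrix()`.
#' @export
write_genotype_matrix <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a table as TSV with header
#'
#' @param table A data frame.
#' @param path Output path.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
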