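#' Define a genome by chromosome lengths
#'
#' A genome definition is the minimal reference the pipeline needs: chromosome
#' names, their lengths in bp, and which chromosomes are autosomes versus sex
#' chromosomes. Coordinates throughout the package are 1-based inclusive.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp. Names are
#'   normalized to the `chr` prefix (`"1"` becomes `"chr1"`).
#' @param sex_chroms Character vector naming the sex chromosomes (default
#'   `"chrX"` and `"chrY"` where present). Everything else is an autosome.
#' @return An object of class `genome_def` with elements `lengths`,
#'   `autosomes`, `sex_chroms`.
#' @examples
#' g <- genome_def(c(chr1 = 2e7, chr2 = 2e7, chrX = 2e7))
#' g$autosomes
#' @export
genome_def <- function(lengths, sex_chroms = c("chrX", "chrY")) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("'lengths' must be a named vector of chromosome lengths")
  names(lengths) <- normalize_chrom(names(lengths))
  if (anyDuplicated(names(lengths)))
    stop("duplicate chromosome names in genome definition")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all chromosome lengths must be positive")
  sex_chroms <- intersect(normalize_chrom(sex_chroms), names(lengths))
  structure(
    list(
      lengths = lengths,
      autosomes = setdiff(names(lengths), sex_chroms),
      sex_chroms = sex_chroms
    ),
    class = "genome_def"
  )
}

#' @export
print.genome_def <- function(x, ...) {
  cat("Genome definition:", length(x$lengths), "chromosomes,",
      format(sum(x$lengths), big.mark = ","), "bp total\n")
  cat("  autosomes:", paste(x$autosomes, collapse = ", "), "\n")
  if (length(x$sex_chroms))
    cat("  sex chromosomes:", paste(x$sex_chroms, collapse = ", "), "\n")
  invisible(x)
}

# "1"/"chr1"/"Chr1" -> "chr1"; "MT" left as chrMT
normalize_chrom <- function(x) {
  x <- as.character(x)
  has <- grepl("^chr", x, ignore.case = TRUE)
  x[has] <- sub("^[Cc][Hh][Rr]", "chr", x[has])
  x[!has] <- paste0("chr", x[!has])
  x
}

chrom_length <- function(genome, chrom) {
  len <- genome$lengths[chrom]
  if (any(is.na(len)))
    stop("unknown chromosome: ", paste(chrom[is.na(len)], collapse = ", "))
  unname(len)
}

#' Expected baseline copy number for a chromosome given sample sex
#'
#' Autosomes have baseline 2 in all samples. The X chromosome has baseline 1
#' in males and 2 in females; the Y chromosome baseline is 1 in males and 0 in
#' females.
#'
#' @param chrom Chromosome name(s).
#' @param sex `"M"` or `"F"` (recycled against `chrom`).
#' @param genome A [genome_def()].
#' @return Integer vector of baseline copy numbers.
#' @export
baseline_copy_number <- function(chrom, sex, genome) {
  chrom <- normalize_chrom(chrom)
  n <- max(length(chrom), length(sex))
  chrom <- rep_len(chrom, n)
  sex <- rep_len(sex, n)
  if (!all(sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  base <- rep.int(2L, n)
  isx <- chrom == "chrX"
  isy <- chrom == "chrY"
  base[isx & sex == "M"] <- 1L
  base[isy] <- ifelse(sex[isy] == "M", 1L, 0L)
  unknown <- !chrom %in% names(genome$lengths)
  if (any(unknown))
    stop("unknown chromosome: ", paste(unique(chrom[unknown]), collapse = ", "))
  base
}

#' Write / read a chromosome-length table
#'
#' Two-column tab-separated table (`chrom`, `length`) plus an optional third
#' column marking sex chromosomes.
#'
#' @param genome A [genome_def()].
#' @param path File path.
#' @return `read_genome_table()` returns a [genome_def()].
#' @export
write_genome_table <- function(genome, path) {
  df <- data.frame(
    chrom = names(genome$lengths),
    length = unname(genome$lengths),
    is_sex = names(genome$lengths) %in% genome$sex_chroms
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genome_table
#' @export
read_genome_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "length") %in% names(df)))
    stop("genome table requires columns 'chrom' and 'length'")
  lens <- stats::setNames(as.numeric(df$length), df$chrom)
  sex <- if ("is_sex" %in% names(df)) df$chrom[as.logical(df$is_sex)] else c("chrX", "chrY")
  genome_def(lens, sex_chroms = sex)
}
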