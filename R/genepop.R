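#' Read a GENEPOP file
#'
#' Parses the 2- and 3-digit diploid GENEPOP dialects (biallelic allele
#' codes 01/02 or 001/002; 00/000 = missing; comma after individual names;
#' `POP` delimiters). Population labels are taken from the shared prefix
#' of individual names before the last underscore when one exists,
#' otherwise `POP1`, `POP2`, ...
#'
#' @param path GENEPOP file path.
#' @return A [genotype_dataset()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) abort("GENEPOP file too short")
  body <- lines[-1] # first line is the title
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) abort("GENEPOP file has no POP line")
  locus_lines <- body[seq_len(first_pop - 1)]
  loci <- unlist(strsplit(paste(locus_lines, collapse = ","), ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  n_loci <- length(loci)

  pop_idx <- cumsum(is_pop)
  rows <- which(!is_pop & pop_idx >= 1)
  ids <- character(0); popn <- integer(0)
  geno <- matrix(NA_integer_, 0, n_loci)
  digits <- NA_integer_
  gmat <- list()
  for (k in rows) {
    line <- body[k]
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2)
      abort(sprintf("line %d: expected 'name , genotypes'", k + 1))
    id <- trimws(parts[1])
    gstr <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                     "\\s+")[[1]]
    gstr <- gstr[nzchar(gstr)]
    if (length(gstr) != n_loci)
      abort(sprintf("line %d: %d genotype field(s), expected %d",
                    k + 1, length(gstr), n_loci))
    w <- unique(nchar(gstr))
    if (length(w) != 1 || !w %in% c(4, 6))
      abort(sprintf(
        "line %d: allele fields must be 4 (2-digit) or 6 (3-digit) characters wide",
        k + 1))
    if (is.na(digits)) digits <- w / 2
    if (digits != w / 2)
      abort(sprintf("line %d: mixed allele dialects", k + 1))
    a1 <- as.integer(substr(gstr, 1, digits))
    a2 <- as.integer(substr(gstr, digits + 1, 2 * digits))
    if (any(a1 > 2 | a2 > 2, na.rm = TRUE))
      abort("only biallelic codes 1/2 (0 = missing) are supported")
    g <- ifelse(a1 == 0 | a2 == 0, NA_integer_,
                (a1 == 2) + (a2 == 2))
    ids <- c(ids, id); popn <- c(popn, pop_idx[k])
    gmat[[length(gmat) + 1]] <- g
  }
  geno <- do.call(rbind, gmat)
  pop_labels <- vapply(seq_len(max(popn)), function(pi) {
    nm <- ids[popn == pi]
    pre <- unique(sub("_[^_]*$", "", nm))
    if (length(pre) == 1 && pre[1] != nm[1]) pre else sprintf("POP%d", pi)
  }, character(1))
  # locus names may encode the SNP position as "<locus>_p<pos>"
  has_pos <- grepl("_p\\d+$", loci)
  snps <- tibble(
    locus = ifelse(has_pos, sub("_p\\d+$", "", loci), loci),
    pos = ifelse(has_pos, as.integer(sub("^.*_p", "", loci)), 1L))
  genotype_dataset(geno, tibble(id = ids, pop = pop_labels[popn]), snps)
}

#' Write a GENEPOP file
#'
#' Writes the biallelic dataset with allele codes 01/02 (2-digit dialect,
#' default) or 001/002, 00/000 for missing, one locus name per line
#' (encoding SNP positions as `<locus>_p<pos>`), and POP-delimited
#' population blocks. `read_genepop()` of the output round-trips the
#' dataset.
#'
#' @param dataset A [genotype_dataset()].
#' @param path Output path.
#' @param digits 2 or 3 (allele-code width).
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(dataset, path, digits = 2,
                          title = "seascaper export") {
  stopifnot(digits %in% c(2, 3))
  fmt <- function(a) formatC(a, width = digits, flag = "0")
  g <- dataset$geno
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(colnames(g), con)
  for (pp in unique(dataset$ind$pop)) {
    writeLines("POP", con)
    for (i in which(dataset$ind$pop == pp)) {
      gi <- g[i, ]
      a1 <- ifelse(is.na(gi), 0L, ifelse(gi >= 1, 2L, 1L))
      a2 <- ifelse(is.na(gi), 0L, ifelse(gi == 2, 2L, 1L))
      writeLines(sprintf("%s ,  %s", dataset$ind$id[i],
                         paste0(fmt(a1), fmt(a2), collapse = " ")), con)
    }
  }
  invisible(path)
}
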