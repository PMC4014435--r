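## Readers/writers: EIGENSTRAT triple, VCF (bi-allelic SNP subset),
## TSV frequency tables, BED masks, samtools-style text pileups.
##
## Dialect notes:
##  * .geno is the dense text variant (one row per SNP, digits 0/1/2/9,
##    9 = missing); values are ALT-allele counts.
##  * .snp carries the 6 standard columns (id, chrom, genetic pos,
##    physical pos, ref, alt) plus two optional extras: ancestral allele
##    ("-" = unknown) and ascertainment tags ("-" = none).
##  * .ind carries id, sex (always "U" on write), population, plus two
##    optional extras: class (modern/ancient/archaic) and ploidy.
##  * VCF support is restricted to bi-allelic SNPs with a GT field;
##    other records are skipped and counted.

#' Read a genotype panel
#'
#' @param path for `eigenstrat`, the common prefix of the `.geno`/`.snp`/
#'   `.ind` triple; for `vcf`, a plain-text VCF file.
#' @param format `"eigenstrat"` or `"vcf"`.
#' @return a [genotype_panel()].  For VCF input, diploid GTs map to
#'   alt-allele counts, `./.` to missing; non-bi-allelic or non-SNP
#'   records are skipped (count reported via `attr(panel, "skipped")`).
#' @export
read_genotypes <- function(path, format = c("eigenstrat", "vcf")) {
  format <- match.arg(format)
  switch(format,
         eigenstrat = read_eigenstrat(path),
         vcf = read_vcf_panel(path))
}

#' Write a genotype panel
#'
#' @param panel a [genotype_panel()].
#' @param path output prefix (eigenstrat) or file (vcf).
#' @param format `"eigenstrat"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path, format = c("eigenstrat", "vcf")) {
  format <- match.arg(format)
  switch(format,
         eigenstrat = write_eigenstrat(panel, path),
         vcf = write_vcf_panel(panel, path))
  invisible(path)
}

read_eigenstrat <- function(prefix) {
  files <- paste0(prefix, c(".geno", ".snp", ".ind"))
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("missing EIGENSTRAT file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!any(nzchar(readLines(files[2])))) {
    snps <- snp_table(character(0), character(0), integer(0),
                      character(0), character(0))
  } else {
    snp <- read.table(files[2], header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character")
    if (ncol(snp) < 6) stop(".snp file needs >= 6 columns", call. = FALSE)
    anc <- if (ncol(snp) >= 7) ifelse(snp[[7]] == "-", NA, snp[[7]]) else NA
    tags <- if (ncol(snp) >= 8) ifelse(snp[[8]] == "-", "", snp[[8]]) else ""
    snps <- snp_table(snp[[1]], snp[[2]], as.integer(snp[[4]]),
                      snp[[5]], snp[[6]], anc, tags)
  }

  ind <- read.table(files[3], header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(ind) < 3) stop(".ind file needs >= 3 columns", call. = FALSE)
  individuals <- data.frame(
    id = ind[[1]], pop = ind[[3]],
    class = if (ncol(ind) >= 4) ind[[4]] else "modern",
    ploidy = if (ncol(ind) >= 5) as.integer(ind[[5]]) else 2L,
    stringsAsFactors = FALSE
  )

  lines <- readLines(files[1])
  lines <- lines[nzchar(lines)]
  if (length(lines) != nrow(snps)) {
    stop(sprintf(".geno has %d rows but .snp has %d SNPs",
                 length(lines), nrow(snps)), call. = FALSE)
  }
  widths <- nchar(lines)
  if (length(lines) && any(widths != nrow(individuals))) {
    stop(sprintf(".geno has %d columns but .ind has %d rows",
                 widths[widths != nrow(individuals)][1], nrow(individuals)),
         call. = FALSE)
  }
  g <- matrix(NA_integer_, nrow(individuals), nrow(snps))
  if (length(lines)) {
    code <- c("0" = 0L, "1" = 1L, "2" = 2L, "9" = NA_integer_)
    digits <- vapply(strsplit(lines, "", fixed = TRUE),
                     function(x) {
                       if (!all(x %in% names(code))) {
                         stop("unparseable .geno character", call. = FALSE)
                       }
                       code[x]
                     }, integer(nrow(individuals)))
    # digits: individuals x snps (vapply binds one column per .geno row)
    g <- matrix(as.integer(digits), nrow(individuals), nrow(snps))
  }
  genotype_panel(snps, individuals, g)
}

write_eigenstrat <- function(panel, prefix) {
  g <- panel$genotypes
  g[is.na(g)] <- 9L
  lines <- vapply(seq_len(ncol(g)), function(j) {
    paste0(g[, j], collapse = "")
  }, character(1))
  writeLines(lines, paste0(prefix, ".geno"))
  s <- panel$snps
  snp_out <- data.frame(s$id, s$chrom, rep("0.0", nrow(s)), s$pos, s$ref,
                        s$alt, ifelse(is.na(s$anc), "-", s$anc),
                        ifelse(s$tags == "", "-", s$tags))
  write.table(snp_out, paste0(prefix, ".snp"), quote = FALSE,
              row.names = FALSE, col.names = FALSE, sep = "\t")
  i <- panel$individuals
  ind_out <- data.frame(i$id, "U", i$pop, i$class, i$ploidy)
  write.table(ind_out, paste0(prefix, ".ind"), quote = FALSE,
              row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

read_vcf_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF lacks a GT field", call. = FALSE)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  nalt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[nalt == 1] <- as.character(unlist(altl[nalt == 1]))
  ok <- nalt == 1 & ref %in% BASES & alt1 %in% BASES
  skipped <- sum(!ok)
  ids <- names(rr)
  if (anyDuplicated(ids[ok])) {
    stop("duplicate SNP id in VCF: ", ids[ok][duplicated(ids[ok])][1],
         call. = FALSE)
  }
  snps <- snp_table(ids[ok],
                    as.character(GenomicRanges::seqnames(rr))[ok],
                    GenomicRanges::start(rr)[ok], ref[ok], alt1[ok])
  gt <- gt[ok, , drop = FALSE]
  counts <- gt_to_count(gt)
  individuals <- data.frame(id = colnames(gt), pop = "unknown",
                            class = "modern",
                            ploidy = ploidy_from_gt(gt),
                            stringsAsFactors = FALSE)
  panel <- genotype_panel(snps, individuals, t(counts))
  attr(panel, "skipped") <- skipped
  panel
}

gt_to_count <- function(gt) {
  u <- unique(as.vector(gt))
  cnt <- vapply(u, function(s) {
    a <- strsplit(s, "[/|]")[[1]]
    if (any(a == ".") || !length(a)) return(NA_integer_)
    sum(as.integer(a))
  }, integer(1))
  matrix(cnt[match(as.vector(gt), u)], nrow(gt), ncol(gt))
}

ploidy_from_gt <- function(gt) {
  apply(gt, 2, function(col) {
    n <- lengths(strsplit(col, "[/|]"))
    if (all(n == 1)) 1L else 2L
  })
}

write_vcf_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=palaeopop",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$individuals$id),
                     collapse = "\t")), con)
  g <- panel$genotypes
  ploidy <- panel$individuals$ploidy
  for (j in seq_len(n_snp(panel))) {
    gts <- character(n_ind(panel))
    for (i in seq_len(n_ind(panel))) {
      x <- g[i, j]
      gts[i] <- if (ploidy[i] == 1L) {
        if (is.na(x)) "." else as.character(x)
      } else {
        if (is.na(x)) "./." else c("0/0", "0/1", "1/1")[x + 1L]
      }
    }
    s <- panel$snps[j, ]
    writeLines(paste(c(s$chrom, s$pos, s$id, s$ref, s$alt, ".", "PASS",
                       ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a population allele-frequency table
#'
#' Expected TSV header: `snp chrom pos ref alt anc` followed by a
#' `<pop>_der` / `<pop>_tot` column pair per population.  `anc` may be
#' `-` for unknown.
#'
#' @param path TSV file.
#' @return a [frequency_panel()].
#' @export
read_frequency_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   comment.char = "#", colClasses = "character")
  num_cols <- setdiff(names(df), c("snp", "chrom", "ref", "alt", "anc"))
  df[num_cols] <- lapply(df[num_cols], as.integer)
  need <- c("snp", "chrom", "pos", "ref", "alt", "anc")
  if (!all(need %in% names(df))) {
    stop("frequency table must have columns ",
         paste(need, collapse = " "), call. = FALSE)
  }
  der_cols <- grep("_der$", names(df), value = TRUE)
  pops <- sub("_der$", "", der_cols)
  tot_cols <- paste0(pops, "_tot")
  if (!all(tot_cols %in% names(df))) {
    stop("missing _tot column for population ",
         pops[!(tot_cols %in% names(df))][1], call. = FALSE)
  }
  snps <- snp_table(df$snp, df$chrom, df$pos, df$ref, df$alt,
                    ifelse(df$anc == "-", NA, df$anc))
  der <- t(as.matrix(df[der_cols])); tot <- t(as.matrix(df[tot_cols]))
  frequency_panel(snps, pops, der, tot)
}

#' Write a population allele-frequency table
#'
#' Inverse of [read_frequency_table()].
#'
#' @param fp a [frequency_panel()].
#' @param path output TSV file.
#' @param header_lines optional `#`-prefixed metadata lines.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(fp, path, header_lines = character()) {
  df <- data.frame(snp = fp$snps$id, chrom = fp$snps$chrom,
                   pos = fp$snps$pos, ref = fp$snps$ref, alt = fp$snps$alt,
                   anc = ifelse(is.na(fp$snps$anc), "-", fp$snps$anc),
                   check.names = FALSE)
  for (k in seq_along(fp$populations)) {
    df[[paste0(fp$populations[k], "_der")]] <- fp$derived[k, ]
    df[[paste0(fp$populations[k], "_tot")]] <- fp$total[k, ]
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  write.table(df, con, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a BED interval file
#'
#' @param path BED file (first three columns chrom, start, end; 0-based,
#'   half-open).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  bed <- data.frame(chrom = as.character(df[[1]]),
                    start = as.numeric(df[[2]]), end = as.numeric(df[[3]]),
                    stringsAsFactors = FALSE)
  if (any(bed$start >= bed$end)) {
    stop("malformed interval: start >= end", call. = FALSE)
  }
  bed
}

#' Read a samtools-style text pileup
#'
#' Accepts the 6-column `samtools mpileup` layout (chrom, pos, ref, depth,
#' bases, base qualities) or the 7-column dialect with a mapping-quality
#' string appended (`mpileup -s`).  Base strings are parsed for `.`/`,`
#' (reference match), explicit bases, `^X` read starts, `$` read ends,
#' `*` deletions and `+N`/`-N` indel segments.  Qualities are
#' Phred+33-encoded characters.  When no mapping-quality column is
#' present, MQ defaults to 60.
#'
#' @param path pileup file.
#' @return data.frame of class `pileup` with columns `chrom`, `pos`,
#'   `ref` and list-columns `bases`, `bq`, `mq` (one vector per site).
#' @export
read_pileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 6)) stop("pileup needs >= 6 columns", call. = FALSE)
  out <- data.frame(
    chrom = vapply(parts, `[[`, "", 1),
    pos = as.integer(vapply(parts, `[[`, "", 2)),
    ref = toupper(vapply(parts, `[[`, "", 3)),
    stringsAsFactors = FALSE
  )
  n <- length(parts)
  bases <- vector("list", n); bq <- vector("list", n); mq <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (as.integer(p[4]) == 0L) {  # zero depth: samtools writes "*" fields
      bases[[i]] <- character(0); bq[[i]] <- integer(0); mq[[i]] <- integer(0)
      next
    }
    b <- parse_pileup_bases(p[5], out$ref[i])
    q <- utf8ToInt(p[6]) - 33L
    m <- if (length(p) >= 7 && nzchar(p[7])) utf8ToInt(p[7]) - 33L
         else rep(60L, length(q))
    # deletions ('*') consume a quality slot; drop them in step
    keep <- b != "*"
    if (length(q) != length(b)) {
      stop("pileup base/quality length mismatch at line ", i, call. = FALSE)
    }
    bases[[i]] <- b[keep]; bq[[i]] <- q[keep]
    mq[[i]] <- rep_len(m, length(b))[keep]
  }
  out$bases <- bases; out$bq <- bq; out$mq <- mq
  class(out) <- c("pileup", "data.frame")
  out
}

parse_pileup_bases <- function(s, ref) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L                      # caret + mapping-quality char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch %in% c("+", "-")) {  # indel: +N<seq> / -N<seq>
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- as.integer(paste0(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
    } else if (ch %in% c(".", ",")) {
      out <- c(out, ref); i <- i + 1L
    } else if (ch == "*") {
      out <- c(out, "*"); i <- i + 1L
    } else {
      out <- c(out, toupper(ch)); i <- i + 1L
    }
  }
  out
}

#' Write a text pileup
#'
#' Emits the 7-column dialect accepted by [read_pileup()] (base and
#' mapping qualities Phred+33 encoded; all bases written explicitly).
#'
#' @param pu a `pileup` data.frame (see [read_pileup()], [simulate_pileup()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pu, path) {
  lines <- vapply(seq_len(nrow(pu)), function(i) {
    b <- pu$bases[[i]]
    if (!length(b)) {
      return(paste(pu$chrom[i], pu$pos[i], pu$ref[i], 0, "*", "*", "*",
                   sep = "\t"))
    }
    paste(pu$chrom[i], pu$pos[i], pu$ref[i], length(b),
          paste0(b, collapse = ""),
          intToUtf8(pu$bq[[i]] + 33L),
          intToUtf8(pu$mq[[i]] + 33L),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
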