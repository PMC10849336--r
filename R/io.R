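# Readers/writers: samtools-mpileup text, the pileup TSV dialect, VCF,
# and BED-derived site lists. All coordinates are 1-based internally
# (VCF/mpileup native); BED input is converted at the boundary.

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

#' Read samtools-mpileup text restricted to panel sites
#'
#' Parses the classic 6-column mpileup text format (CHROM, POS, REF, DEPTH,
#' read bases, base qualities). In the read-bases string, `.` and `,` count
#' toward the reference allele; `ACGT` (either case) counts toward the
#' alternate allele when it matches the site's alternate, otherwise toward
#' `other_count`; `^` (plus the following mapping-quality character) and `$`
#' are read-segment markers and consumed; `+n`/`-n` indel runs are skipped;
#' `*`, `<` and `>` consume their quality character but count toward
#' nothing. Base qualities are Phred, ASCII offset 33; bases below
#' `min_base_quality` are dropped. Panel sites absent from the file yield
#' zero-count records so covered-fraction denominators are correct.
#'
#' The reader assumes duplicates were excluded upstream (e.g. samtools
#' mpileup `--ff DUP`); `dup_count` is zero for mpileup input and only
#' populated by the TSV dialect or the simulator.
#'
#' @param path Path to mpileup text.
#' @param sites Site list data.frame (`chrom`, `pos`, `ref`, `alt`).
#' @param min_base_quality Minimum Phred base quality (default 13).
#' @param strict If `TRUE`, a pileup line at a position not in `sites` is an
#'   error; otherwise it is skipped with a warning.
#' @return A `site_pileup` data.frame aligned to `sites`.
#' @export
read_mpileup <- function(path, sites, min_base_quality = 13L,
                         strict = FALSE) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n <- nrow(sites)
  ref_count <- alt_count <- other_count <- raw_depth <- integer(n)
  lookup <- stats::setNames(seq_len(n), site_key(sites$chrom, sites$pos))

  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 6L) {
      # zero-depth lines may omit the bases/quals columns
      if (length(f) >= 4L && f[4L] == "0") next
      stop("malformed mpileup line ", ln, ": expected 6 columns")
    }
    idx <- lookup[site_key(f[1L], f[2L])]
    if (is.na(idx)) {
      msg <- paste0("mpileup line ", ln, ": site ", f[1L], ":", f[2L],
                    " not in the site list")
      if (strict) stop(msg)
      warning(msg, "; skipped")
      next
    }
    parsed <- parse_pileup_bases(f[5L], f[6L], line = ln)
    keep <- parsed$qual >= min_base_quality
    base <- toupper(parsed$base[keep])
    ref_count[idx] <- sum(base == "R")
    alt_count[idx] <- sum(base == toupper(sites$alt[idx]))
    other_count[idx] <- sum(base != "R" & base != toupper(sites$alt[idx]))
    raw_depth[idx] <- as.integer(f[4L])
  }
  out <- data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    ref_count = ref_count, alt_count = alt_count, other_count = other_count,
    raw_depth = raw_depth, dup_count = 0L, stringsAsFactors = FALSE
  )
  class(out) <- c("site_pileup", "data.frame")
  out
}

# Decode one mpileup read-bases string against its quality string.
# Returns per counted base: base ("R" for ref match, otherwise the letter,
# NA for */<_/> placeholders) and Phred quality. Errors on base/quality
# length mismatch.
parse_pileup_bases <- function(bases, quals, line = NA) {
  ch <- strsplit(bases, "", fixed = TRUE)[[1L]]
  qch <- strsplit(quals, "", fixed = TRUE)[[1L]]
  out_base <- character(0)
  out_qual <- integer(0)
  i <- 1L
  qi <- 1L
  take_qual <- function() {
    if (qi > length(qch)) {
      stop("mpileup line ", line, ": base/quality length mismatch")
    }
    q <- utf8ToInt(qch[qi]) - 33L
    qi <<- qi + 1L
    q
  }
  while (i <= length(ch)) {
    c0 <- ch[i]
    if (c0 == "^") {
      i <- i + 2L                      # caret + mapping quality char
    } else if (c0 == "$") {
      i <- i + 1L
    } else if (c0 == "+" || c0 == "-") {
      j <- i + 1L
      while (j <= length(ch) && grepl("[0-9]", ch[j])) j <- j + 1L
      nlen <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + nlen                    # skip the inserted/deleted sequence
    } else if (c0 == "." || c0 == ",") {
      out_base <- c(out_base, "R")
      out_qual <- c(out_qual, take_qual())
      i <- i + 1L
    } else if (grepl("[ACGTNacgtn]", c0)) {
      out_base <- c(out_base, toupper(c0))
      out_qual <- c(out_qual, take_qual())
      i <- i + 1L
    } else if (c0 %in% c("*", "<", ">")) {
      take_qual()                      # placeholder consumes a quality
      i <- i + 1L
    } else {
      stop("mpileup line ", line, ": unexpected character '", c0, "'")
    }
  }
  if (qi != length(qch) + 1L) {
    stop("mpileup line ", line, ": base/quality length mismatch")
  }
  list(base = out_base, qual = out_qual)
}

#' Write simulated pileups as samtools-mpileup text
#'
#' Writes the unique (deduplicated) reads of a simulated pileup in the
#' 6-column mpileup text format. Requires read-level data, i.e. a pileup
#' produced with `simulate_pileup(..., keep_reads = TRUE)`. Zero-read sites
#' are omitted, as samtools does without `-a`.
#'
#' @param pileups A `site_pileup` with a `"reads"` attribute.
#' @param path Output path.
#' @param reads Optional explicit read-level data.frame (`site`, `base`,
#'   `qual`) overriding the attribute.
#' @return `path`, invisibly.
#' @export
write_mpileup <- function(pileups, path, reads = attr(pileups, "reads")) {
  if (is.null(reads)) {
    stop("read-level data required; simulate with keep_reads = TRUE")
  }
  by_site <- split(seq_len(nrow(reads)), reads$site)
  lines <- vapply(names(by_site), function(s) {
    i <- as.integer(s)
    rows <- by_site[[s]]
    b <- ifelse(reads$base[rows] == pileups$ref[i], ".", reads$base[rows])
    q <- intToUtf8(reads$qual[rows] + 33L, multiple = FALSE)
    paste(pileups$chrom[i], pileups$pos[i], pileups$ref[i],
          length(rows), paste(b, collapse = ""), q, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write the pileup TSV dialect
#'
#' The pipeline's native interchange: a header line plus one row per panel
#' site with columns CHROM, POS, REF, ALT, REF_COUNT, ALT_COUNT, OTHER,
#' RAW_DEPTH, DUP_COUNT. Unlike mpileup text it is lossless about duplicate
#' tallies.
#'
#' @param pileups A `site_pileup` data.frame.
#' @param path File path.
#' @return `write_pileup_tsv` returns `path` invisibly; `read_pileup_tsv`
#'   returns a `site_pileup` data.frame.
#' @export
write_pileup_tsv <- function(pileups, path) {
  out <- data.frame(
    CHROM = pileups$chrom, POS = pileups$pos, REF = pileups$ref,
    ALT = pileups$alt, REF_COUNT = pileups$ref_count,
    ALT_COUNT = pileups$alt_count, OTHER = pileups$other_count,
    RAW_DEPTH = pileups$raw_depth, DUP_COUNT = pileups$dup_count
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "integer", "character",
                                        "character", "integer", "integer",
                                        "integer", "integer", "integer"))
  out <- data.frame(
    chrom = d$CHROM, pos = d$POS, ref = d$REF, alt = d$ALT,
    ref_count = d$REF_COUNT, alt_count = d$ALT_COUNT,
    other_count = d$OTHER, raw_depth = d$RAW_DEPTH,
    dup_count = d$DUP_COUNT, stringsAsFactors = FALSE
  )
  if (any(out$ref_count + out$alt_count + out$other_count > out$raw_depth)) {
    stop("invalid pileup TSV: filtered counts exceed raw depth")
  }
  class(out) <- c("site_pileup", "data.frame")
  out
}

#' Write genotype calls (and posteriors) as VCF 4.2
#'
#' Writes one sample. When `posteriors` is supplied a GP FORMAT field with
#' the three genotype posteriors (6 decimal places) is included, and sites
#' flagged in `low_confidence` get FILTER `LOWCONF` (others `PASS`).
#' Missing calls (`NA`) are written as `./.`.
#'
#' @param sites Site list data.frame (`chrom`, `pos`, `ref`, `alt`).
#' @param calls Integer genotypes in 0:2, `NA` for missing.
#' @param path Output path.
#' @param posteriors Optional n x 3 posterior matrix.
#' @param low_confidence Optional logical vector driving the LOWCONF filter.
#' @param af Optional per-site allele frequency written as `AF=` INFO.
#' @param sample Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, calls, path, posteriors = NULL,
                      low_confidence = NULL, af = NULL, sample = "SAMPLE") {
  n <- nrow(sites)
  stopifnot(length(calls) == n)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=lpimpute",
    "##FILTER=<ID=LOWCONF,Description=\"No genotype posterior greater than the confidence threshold\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  if (!is.null(posteriors)) {
    header <- c(header,
      "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype posterior probabilities\">")
  }
  if (!is.null(af)) {
    header <- c(header,
      "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">")
  }
  header <- c(header, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                            "FILTER", "INFO", "FORMAT", sample, sep = "\t"))
  if (n == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  gt <- c("0/0", "0/1", "1/1")[calls + 1L]
  gt[is.na(calls)] <- "./."
  filt <- if (is.null(low_confidence)) {
    rep(".", n)
  } else {
    ifelse(low_confidence, "LOWCONF", "PASS")
  }
  info <- if (is.null(af)) rep(".", n) else sprintf("AF=%.6g", af)
  if (is.null(posteriors)) {
    fmt <- "GT"
    samp <- gt
  } else {
    stopifnot(nrow(posteriors) == n, ncol(posteriors) == 3L)
    fmt <- "GT:GP"
    samp <- paste0(gt, ":", sprintf("%.6f,%.6f,%.6f", posteriors[, 1L],
                                    posteriors[, 2L], posteriors[, 3L]))
  }
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                filt, info, fmt, samp, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a haplotype panel as a phased VCF
#'
#' Haplotypes 2k-1 and 2k form diploid sample `H<k>` with phased genotypes;
#' per-site alternate-allele frequency is written to the AF INFO field.
#'
#' @param panel A `haplotype_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  validate_panel(panel)
  a <- panel$alleles
  n_ind <- nrow(a) / 2L
  samples <- paste0("H", seq_len(n_ind))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=lpimpute",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_cols <- vapply(seq_len(n_ind), function(k) {
    paste0(a[2L * k - 1L, ], "|", a[2L * k, ])
  }, character(ncol(a)))
  body <- paste(panel$sites$chrom, panel$sites$pos, ".", panel$sites$ref,
                panel$sites$alt, ".", ".", sprintf("AF=%.6g", panel$af),
                "GT", apply(gt_cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotype calls (and GP) from a VCF
#'
#' Reads the first sample of a VCF via vcfR and maps GT to alternate-allele
#' counts in 0:2 (`./.` to `NA`). When `honor_filter` is `TRUE`, records
#' whose FILTER is neither `PASS` nor `.` become `NA`. If `sites` is given,
#' records are aligned to it (panel sites absent from the file are `NA`) and
#' any chromosome/position match with mismatching REF/ALT is an error.
#'
#' @param path VCF path.
#' @param sites Optional site list to align against.
#' @param honor_filter Drop non-PASS records (default `TRUE`).
#' @return List with `calls` (integer, `NA` = missing/filtered), `gp`
#'   (n x 3 matrix or `NULL`), and `sites` (the site data.frame used).
#' @export
read_vcf_genotypes <- function(path, sites = NULL, honor_filter = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    empty <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character())
    return(list(calls = integer(0), gp = NULL,
                sites = if (is.null(sites)) empty else sites))
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")[, 1L]
  calls <- vapply(strsplit(gt_raw, "[/|]"), function(x) {
    if (any(is.na(x)) || any(x == ".")) NA_integer_ else sum(x == "1")
  }, integer(1))
  if (honor_filter) {
    calls[!(fix$FILTER %in% c("PASS", ".") | is.na(fix$FILTER))] <- NA_integer_
  }
  gp <- NULL
  if ("GP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    gp_raw <- vcfR::extract.gt(v, element = "GP")[, 1L]
    gp <- t(vapply(strsplit(gp_raw, ",", fixed = TRUE),
                   function(x) as.numeric(x), numeric(3)))
    colnames(gp) <- c("hom_ref", "het", "hom_alt")
  }
  rec_sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                          ref = fix$REF, alt = fix$ALT,
                          stringsAsFactors = FALSE)
  if (!is.null(sites)) {
    idx <- match(site_key(sites$chrom, sites$pos),
                 site_key(rec_sites$chrom, rec_sites$pos))
    hit <- !is.na(idx)
    bad <- hit & (rec_sites$ref[idx] != sites$ref |
                    rec_sites$alt[idx] != sites$alt)
    bad[is.na(bad)] <- FALSE
    if (any(bad)) {
      stop("REF/ALT mismatch vs site list at: ",
           paste(site_key(sites$chrom[bad], sites$pos[bad]), collapse = ", "))
    }
    aligned <- rep(NA_integer_, nrow(sites))
    aligned[hit] <- calls[idx[hit]]
    calls <- aligned
    if (!is.null(gp)) {
      g2 <- matrix(NA_real_, nrow(sites), 3L,
                   dimnames = list(NULL, colnames(gp)))
      g2[hit, ] <- gp[idx[hit], , drop = FALSE]
      gp <- g2
    }
    rec_sites <- sites
  }
  list(calls = calls, gp = gp, sites = rec_sites)
}

#' Site list from a BED-like file
#'
#' Reads a tab-separated BED-like file with columns chrom, start, end, ref,
#' alt (half-open 0-based intervals) and converts to the package's 1-based
#' site convention (`pos = start + 1`). Every interval must span exactly one
#' base.
#'
#' @param path File path.
#' @return A site list data.frame (`chrom`, `pos`, `ref`, `alt`).
#' @export
sites_from_bed <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "start", "end", "ref", "alt"),
                         colClasses = c("character", "integer", "integer",
                                        "character", "character"))
  if (any(d$end - d$start != 1L)) {
    stop("BED site intervals must span exactly one base (SNPs)")
  }
  data.frame(chrom = d$chrom, pos = d$start + 1L, ref = d$ref, alt = d$alt,
             stringsAsFactors = FALSE)
}
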