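#' Read a FASTA file into a tibble
#'
#' Parses nucleotide or protein FASTA into one row per record. Nucleotide
#' sequences are uppercased and characters outside `ACGT` are mapped to `N`;
#' protein sequences are returned verbatim.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param type `"dna"`, `"protein"`, or `"auto"` (default), which treats a
#'   record as DNA when at least 90% of its letters are `ACGTN`.
#' @return A tibble with columns `id`, `description`, `sequence`. An empty
#'   file yields a zero-row tibble.
#' @examples
#' tf <- tempfile(fileext = ".fna")
#' writeLines(c(">x some gene", "AC", "GT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, type = c("auto", "dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) == 0L) {
    return(tibble(id = character(), description = character(),
                  sequence = character()))
  }
  if (!startsWith(first[[1]], ">")) {
    abort("FASTA format error: sequence data before the first '>' header")
  }
  set <- Biostrings::readBStringSet(path)
  nm <- names(set)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  seqs <- as.character(set)
  if (any(!nzchar(id))) abort("FASTA format error: empty record id")
  if (any(!nzchar(seqs))) abort("FASTA format error: empty sequence")
  is_dna <- switch(type,
    dna = rep(TRUE, length(seqs)),
    protein = rep(FALSE, length(seqs)),
    auto = {
      up <- toupper(seqs)
      nch <- nchar(up)
      acgtn <- nch - nchar(gsub("[ACGTNacgtn]", "", seqs))
      acgtn / pmax(nch, 1L) >= 0.9
    })
  seqs[is_dna] <- normalize_dna(seqs[is_dna])
  tibble(id = id, description = desc, sequence = unname(seqs))
}

# uppercase and collapse ambiguity codes to N
normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

#' Write sequences to FASTA
#'
#' @param seqs A tibble with `id` and `sequence` columns (optionally
#'   `description`), or a named character vector.
#' @param path Output path.
#' @param width Line width for sequence folding.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) {
    seqs <- tibble(id = names(seqs), description = "", sequence = unname(seqs))
  }
  stopifnot(all(c("id", "sequence") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) seqs$description
          else rep("", nrow(seqs))
  nm <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  set <- Biostrings::BStringSet(setNames(seqs$sequence, nm))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene records from GFF3
#'
#' Extracts coding features as a gene table with 1-based inclusive
#' coordinates, preserved exactly as printed in the file. The `ID` attribute
#' is preferred as the gene identifier, falling back to `locus_tag`.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature types to keep (default `"CDS"`).
#' @return A tibble with columns `gene_id`, `replicon_id`, `start`, `end`,
#'   `strand`, `product`.
#' @export
read_gff3 <- function(path, feature_type = "CDS") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  for (i in body) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) {
      abort(sprintf("GFF3 format error at line %d: expected 9 fields", i))
    }
    s <- suppressWarnings(as.integer(f[[4]]))
    e <- suppressWarnings(as.integer(f[[5]]))
    if (is.na(s) || is.na(e) || e < s) {
      abort(sprintf("GFF3 format error at line %d: end < start (%s..%s)",
                    i, f[[4]], f[[5]]))
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  if (length(gr) == 0L) {
    return(tibble(gene_id = character(), replicon_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  product = character()))
  }
  mc <- as.data.frame(S4Vectors::mcols(gr))
  gid <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  lt <- if ("locus_tag" %in% names(mc)) as.character(mc$locus_tag) else rep(NA_character_, length(gr))
  gid <- ifelse(is.na(gid) | !nzchar(gid), lt, gid)
  if (anyNA(gid)) abort("GFF3 format error: record with neither ID nor locus_tag")
  prod <- if ("product" %in% names(mc)) as.character(mc$product) else ""
  prod[is.na(prod)] <- ""
  out <- tibble(
    gene_id = gid,
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = prod
  )
  if (anyDuplicated(out$gene_id)) {
    abort("GFF3 format error: duplicate gene ids")
  }
  if (any(!out$strand %in% c("+", "-"))) {
    abort("GFF3 format error: coding feature without +/- strand")
  }
  arrange(out, .data$replicon_id, .data$start)
}

#' Write a gene table to GFF3
#'
#' @param genes Tibble as returned by [read_gff3()].
#' @param path Output path.
#' @param feature_type Feature type to stamp on each row.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, feature_type = "CDS") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$type <- feature_type
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  if ("product" %in% names(genes)) gr$product <- genes$product
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a protein-domain hit table
#'
#' Reads a tab-separated domain table (HMMER-tblout-like, one row per domain
#' hit) with columns `protein_id`, `pfam_acc`, `pfam_name`, `ali_start`,
#' `ali_end`, `bitscore`, `evalue`. Lines starting with `#` are ignored.
#' Version suffixes on accessions (`PF00158.27`) are stripped into
#' `pfam_acc`, with the original kept in `pfam_acc_raw`.
#'
#' @param path Path to the TSV file.
#' @return A tibble of domain hits.
#' @export
read_domain_table <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("protein_id", "pfam_acc", "pfam_name", "ali_start", "ali_end",
            "bitscore", "evalue")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    abort(paste0("domain table format error: missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  out <- df %>%
    mutate(
      pfam_acc_raw = as.character(.data$pfam_acc),
      pfam_acc = strip_pfam_version(.data$pfam_acc_raw),
      ali_start = as.integer(.data$ali_start),
      ali_end = as.integer(.data$ali_end),
      bitscore = as.numeric(.data$bitscore),
      evalue = as.numeric(.data$evalue)
    ) %>%
    select("protein_id", "pfam_acc", "pfam_acc_raw", "pfam_name",
           "ali_start", "ali_end", "bitscore", "evalue")
  if (any(out$evalue < 0, na.rm = TRUE)) {
    abort("domain table format error: negative evalue")
  }
  if (any(out$ali_end < out$ali_start)) {
    abort("domain table format error: ali_end < ali_start")
  }
  bad <- !grepl("^PF\\d{5}$", out$pfam_acc)
  if (any(bad)) {
    abort(paste0("domain table format error: malformed accession(s): ",
                 paste(unique(out$pfam_acc[bad]), collapse = ", ")))
  }
  out
}

#' Strip a Pfam accession version suffix
#'
#' `"PF00158.27"` becomes `"PF00158"`; already-bare accessions pass through
#' unchanged (the operation is idempotent).
#'
#' @param acc Character vector of accessions.
#' @return Character vector of bare accessions.
#' @export
strip_pfam_version <- function(acc) {
  sub("\\.\\d+$", "", acc)
}

#' Write a domain table
#' @param hits Tibble of domain hits.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(hits, path) {
  cols <- c("protein_id", "pfam_acc", "pfam_name", "ali_start", "ali_end",
            "bitscore", "evalue")
  if ("pfam_acc_raw" %in% names(hits)) {
    hits <- mutate(hits, pfam_acc = .data$pfam_acc_raw)
  }
  readr::write_tsv(select(hits, dplyr::all_of(cols)), path, progress = FALSE)
  invisible(path)
}

SIMILARITY_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
                     "mismatches", "gap_opens", "q_start", "q_end", "s_start",
                     "s_end", "evalue", "bitscore")

#' Read an all-vs-all protein similarity table
#'
#' Reads the ubiquitous 12-column tabular alignment dialect, optionally with
#' a 13th query-coverage column (percent). When the 13th column is absent,
#' coverage is computed as `100 * aln_length / query_length` from the
#' supplied query lengths.
#'
#' @param path Path to the tabular file (no header).
#' @param query_lengths Optional named numeric vector of query protein
#'   lengths, required when the file has no coverage column.
#' @return A tibble with the 12 standard columns plus `query_coverage`.
#' @export
read_similarity_table <- function(path, query_lengths = NULL) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) {
    empty <- c(as.list(setNames(rep(list(character()), 2),
                                SIMILARITY_COLS[1:2])),
               as.list(setNames(rep(list(numeric()), 10),
                                SIMILARITY_COLS[3:12])))
    return(as_tibble(c(empty, list(query_coverage = numeric()))))
  }
  if (ncol(df) < 12L) {
    abort("similarity table format error: fewer than 12 columns")
  }
  has_cov <- ncol(df) >= 13L
  df <- df[, seq_len(if (has_cov) 13L else 12L)]
  names(df) <- c(SIMILARITY_COLS, if (has_cov) "query_coverage")
  if (!has_cov) {
    if (is.null(query_lengths)) {
      abort(paste0("similarity table has no coverage column; ",
                   "supply `query_lengths` to compute it"))
    }
    qlen <- unname(query_lengths[df$query_id])
    if (anyNA(qlen)) abort("query length missing for some query ids")
    df$query_coverage <- 100 * df$aln_length / qlen
  }
  df <- mutate(df, query_coverage = pmin(.data$query_coverage, 100))
  if (any(df$evalue < 0) || any(df$pct_identity < 0 | df$pct_identity > 100)) {
    abort("similarity table format error: evalue or identity out of range")
  }
  as_tibble(df)
}

#' Write a similarity table (12 + 1 columns)
#' @param hits Tibble of similarity hits.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_table <- function(hits, path) {
  for (col in SIMILARITY_COLS) {
    if (!col %in% names(hits)) hits[[col]] <- 0
  }
  readr::write_tsv(hits[, c(SIMILARITY_COLS, "query_coverage")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write motifs in MEME minimal format
#'
#' Emits a `MEME version 4` file (ACGT alphabet) that standard scanners
#' consume, with one `MOTIF` block and letter-probability matrix per PWM.
#'
#' @param pwms A list of [pwm] objects (or a single one).
#' @param path Output path.
#' @param background Optional [markov_background]; its order-0 marginal is
#'   written as the background letter frequencies (uniform when `NULL`).
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(pwms, path, background = NULL) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  bg <- if (is.null(background)) {
    setNames(rep(0.25, 4), DNA_BASES)
  } else {
    background_marginal(background)
  }
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", DNA_BASES, bg), collapse = " "), ""
  )
  for (p in pwms) {
    stopifnot(inherits(p, "pwm"))
    csums <- colSums(p$matrix)
    if (any(abs(csums - 1) > 1e-6)) {
      abort(sprintf("refusing to write motif '%s': column(s) not normalized",
                    p$motif_id))
    }
    w <- ncol(p$matrix)
    lines <- c(lines,
      paste("MOTIF", p$motif_id),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
              w, p$nsites %||% 0L),
      vapply(seq_len(w), function(j) {
        paste(sprintf("%.6f", p$matrix[, j]), collapse = "  ")
      }, character(1)),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read motifs from MEME minimal format
#'
#' @param path Path to a MEME-format motif file.
#' @return A list of [pwm] objects, with the file's background frequencies
#'   attached as attribute `"background"`.
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^MEME version", lines))) {
    abort("not a MEME motif file: missing 'MEME version' header")
  }
  bg <- setNames(rep(0.25, 4), DNA_BASES)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) > 0L) {
    toks <- strsplit(trimws(lines[[bgl[[1]] + 1L]]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    bg <- setNames(vals, toks[seq(1, length(toks), by = 2)])[DNA_BASES]
  }
  starts <- grep("^MOTIF\\s", lines)
  pwms <- lapply(starts, function(i) {
    motif_id <- strsplit(trimws(lines[[i]]), "\\s+")[[1]][[2]]
    j <- i + 1L
    while (j <= length(lines) && !grepl("^letter-probability matrix", lines[[j]])) {
      j <- j + 1L
    }
    hdr <- lines[[j]]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr)) {
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr))
    } else 0L
    rows <- lines[(j + 1L):(j + w)]
    mat <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(4)))
    new_pwm(t(mat), motif_id = motif_id, nsites = nsites, renormalize = TRUE)
  })
  attr(pwms, "background") <- bg
  pwms
}

#' Write binding-site hits as BED6+1
#'
#' Converts the package's 1-based inclusive hit coordinates to BED's 0-based
#' half-open convention; the hit p-value is written in column 7.
#'
#' @param hits Tibble of site hits with columns `seq_id`, `start`, `end`,
#'   `strand`, `score`, `pvalue` and optionally `motif_id` (used as the BED
#'   name field).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(hits, path) {
  if (nrow(hits) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  name <- if ("motif_id" %in% names(hits)) hits$motif_id else "site"
  bed <- tibble(
    chrom = hits$seq_id,
    start = hits$start - 1L,
    end = hits$end,
    name = name,
    score = hits$score,
    strand = hits$strand,
    pvalue = hits$pvalue
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
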