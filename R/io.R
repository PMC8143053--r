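# Readers and writers for every external format the pipeline touches.
# Conventions: VCF positions are 1-based; BED intervals are 0-based
# half-open; all internal coordinates are 1-based inclusive and converted at
# this boundary. Probe- and variant-to-gene mappings are always taken from
# the input annotations, never recomputed from coordinates. gzip input is
# handled transparently by the underlying readers.

REQUIRED_VARIANT_COLS <- c("id", "chrom", "pos", "ref", "alt", "gene",
                           "func_class", "sift", "maf")

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  if (!is.null(required) && !all(required %in% names(df))) {
    stop("missing required column(s) in ", path, ": ",
         paste(setdiff(required, names(df)), collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a variant set as VCF v4.2
#'
#' Annotations go into the INFO column (keys `GENE`, `FUNC`, `SIFT`, `MAF`);
#' per-sample carrier states become `GT` fields (`0/1` carrier, `0/0`
#' non-carrier).
#'
#' @param vs a `variant_set`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_variants_vcf <- function(vs, path) {
  stopifnot(inherits(vs, "variant_set"))
  v <- vs$variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=FUNC,Number=1,Type=String,Description=\"Functional class\">",
    "##INFO=<ID=SIFT,Number=1,Type=String,Description=\"SIFT call\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vs$samples), collapse = "\t"))
  info <- sprintf("GENE=%s;FUNC=%s;SIFT=%s;MAF=%s",
                  v$gene, v$func_class, v$sift, sprintf("%.17g", v$maf))
  gt <- matrix(ifelse(vs$carriers, "0/1", "0/0"), nrow = nrow(v))
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a variant set as a flat TSV
#'
#' One annotation column per field, then one 0/1 carrier column per sample.
#'
#' @param vs a `variant_set`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_variants_tsv <- function(vs, path) {
  stopifnot(inherits(vs, "variant_set"))
  df <- cbind(vs$variants,
              as.data.frame(vs$carriers * 1L, check.names = FALSE))
  write_tsv(df, path)
}

#' Read case-control variant calls
#'
#' @param path a VCF v4.2 file (INFO keys `GENE`, `FUNC`, `SIFT`, `MAF`;
#'   per-sample `GT`) or the equivalent flat TSV written by
#'   [write_variants_tsv()].
#' @param dialect `"vcf"` or `"tsv"`.
#' @return a `variant_set`. Any sample with a non-reference allele in `GT`
#'   is a carrier; missing genotypes (`./.`) count as non-carriers and the
#'   number of missing calls is reported via a message and stored in the
#'   `n_missing_gt` attribute.
#' @export
read_variants <- function(path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    df <- read_tsv(path, required = REQUIRED_VARIANT_COLS)
    sample_cols <- setdiff(names(df), REQUIRED_VARIANT_COLS)
    carriers <- as.matrix(df[sample_cols]) > 0
    vs <- new_variant_set(df[REQUIRED_VARIANT_COLS], carriers, sample_cols)
    attr(vs, "n_missing_gt") <- 0L
    return(vs)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {  # single-record files drop to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  ann <- data.frame(
    id = fix[, "ID"],
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    gene = vcfR::extract.info(vcf, element = "GENE"),
    func_class = vcfR::extract.info(vcf, element = "FUNC"),
    sift = vcfR::extract.info(vcf, element = "SIFT"),
    maf = vcfR::extract.info(vcf, element = "MAF", as.numeric = TRUE),
    stringsAsFactors = FALSE)
  for (col in c("gene", "sift", "maf")) {
    bad <- which(is.na(ann[[col]]))
    if (length(bad)) {
      stop(sprintf("record %s lacks the required %s annotation",
                   ann$id[bad[1]], toupper(sub("gene", "GENE", col))),
           call. = FALSE)
    }
  }
  ann$func_class[is.na(ann$func_class)] <- "other"
  gt <- vcfR::extract.gt(vcf, element = "GT")
  missing <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  carriers <- !missing & grepl("[1-9]", gt)
  n_missing <- sum(missing)
  if (n_missing > 0) {
    message(n_missing, " missing genotype call(s) treated as non-carrier")
  }
  vs <- new_variant_set(ann, unname(carriers), colnames(gt))
  attr(vs, "n_missing_gt") <- n_missing
  vs
}

#' Read genomic intervals from a 3+ column BED file
#'
#' BED convention: 0-based, half-open. An interval `chrom start end` covers
#' 1-based positions `start+1 .. end`. Overlapping intervals are retained
#' unmerged; a per-chromosome sorted order is applied for indexed lookups.
#'
#' @param path BED file; `track`/`browser`/comment lines are skipped.
#' @return `data.frame(chrom, start, end)` of class `interval_set`.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  iv <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
  if (any(keep)) {
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    lineno <- which(keep)
    nf <- lengths(fields)
    if (any(nf < 3)) {
      stop("BED line ", lineno[which(nf < 3)[1]], " has fewer than 3 columns",
           call. = FALSE)
    }
    iv <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                     start = as.integer(vapply(fields, `[[`, "", 2L)),
                     end = as.integer(vapply(fields, `[[`, "", 3L)),
                     stringsAsFactors = FALSE)
    bad <- which(is.na(iv$start) | is.na(iv$end) | iv$start >= iv$end |
                   !nzchar(iv$chrom))
    if (length(bad)) {
      stop("invalid interval (start >= end or unparseable) at BED line ",
           lineno[bad[1]], call. = FALSE)
    }
    iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
    rownames(iv) <- NULL
  }
  class(iv) <- c("interval_set", "data.frame")
  iv
}

#' Write intervals as 3-column BED (0-based half-open, headerless)
#' @param iv `data.frame(chrom, start, end)`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(iv, path) {
  if (nrow(iv) == 0) {
    writeLines(character(0), path)
  } else {
    writeLines(paste(iv$chrom, iv$start, iv$end, sep = "\t"), path)
  }
  invisible(path)
}

#' Read a beta-value matrix (probes x samples TSV)
#'
#' First column holds probe ids; the header names the samples. All entries
#' must be methylation fractions in \[0, 1\]; duplicate probe or sample ids
#' are rejected.
#'
#' @param path TSV path.
#' @return numeric matrix with probe rownames and sample colnames.
#' @export
read_beta_matrix <- function(path) {
  df <- read_tsv(path)
  probes <- as.character(df[[1]])
  if (anyDuplicated(probes)) {
    stop("duplicate probe id(s): ",
         paste(unique(probes[duplicated(probes)])[1:3], collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(df)[-1])) {
    stop("duplicate sample id(s) in header", call. = FALSE)
  }
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stop("non-numeric beta values", call. = FALSE)
  if (anyNA(m) || any(m < 0) || any(m > 1)) {
    stop("beta values must lie in [0, 1] with no missing entries",
         call. = FALSE)
  }
  rownames(m) <- probes
  m
}

#' Write a beta-value matrix as TSV (rows = probes, header = sample ids)
#' @param beta numeric matrix with dimnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(probe = rownames(beta), beta, check.names = FALSE)
  write_tsv(df, path)
}

#' Read gene sets from a GMT file
#'
#' Each line: `term<TAB>description<TAB>gene1<TAB>gene2...` (at least three
#' fields). Returns a named list of unique gene vectors with descriptions in
#' the `description` attribute.
#'
#' @param path GMT path.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    stop("GMT line ", which(lengths(fields) < 3)[1],
         " has fewer than 3 fields", call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description column (recycled).
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  description <- rep_len(description, length(sets))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read a weighted, undirected edge list
#'
#' TSV with columns `geneA`, `geneB`, `score`. Scores must parse into
#' \[0, 1\]. Self-edges are dropped with a warning; duplicate edges (in
#' either orientation) keep the maximum score.
#'
#' @param path TSV path.
#' @return `data.frame(geneA, geneB, score)`, one row per undirected edge.
#' @export
read_edge_list <- function(path) {
  df <- read_tsv(path, required = c("geneA", "geneB", "score"))
  df$score <- as.numeric(df$score)
  if (anyNA(df$score) || any(df$score < 0) || any(df$score > 1)) {
    stop("edge scores must parse to [0, 1]", call. = FALSE)
  }
  self <- df$geneA == df$geneB
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped", call. = FALSE)
    df <- df[!self, , drop = FALSE]
  }
  a <- pmin(df$geneA, df$geneB); b <- pmax(df$geneA, df$geneB)
  df$geneA <- a; df$geneB <- b
  df <- df[order(a, b, -df$score), , drop = FALSE]
  df <- df[!duplicated(paste(df$geneA, df$geneB)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a probe manifest TSV
#' @param path TSV with columns `probe`, `chrom`, `pos`, `gene`, `feature`,
#'   `island_relation` (1-based probe positions).
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  read_tsv(path, required = c("probe", "chrom", "pos", "gene", "feature",
                              "island_relation"))
}

#' Read a meQTL pair table
#' @param path TSV with columns `chrom`, `pos`, `gene`, `probe`, `mode`
#'   (`cis`/`trans`), one SNP-locus-to-probe link per row.
#' @return data.frame.
#' @export
read_meqtl <- function(path) {
  df <- read_tsv(path, required = c("chrom", "pos", "gene", "probe", "mode"))
  bad <- setdiff(unique(df$mode), c("cis", "trans"))
  if (length(bad)) {
    stop("meQTL mode must be cis/trans, found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a case-control design TSV (columns `sample`, `group`)
#' @param path TSV path.
#' @return data.frame with groups validated to `case`/`control`.
#' @export
read_design <- function(path) {
  df <- read_tsv(path, required = c("sample", "group"))
  design_groups(df)  # validates
  df
}

#' Read a one-symbol-per-line gene list
#' @param path text file.
#' @return character vector (empty lines removed).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}
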