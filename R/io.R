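#' Construct a PositionCounts object
#'
#' @param gene_id gene identifier.
#' @param ribo,rna integer matrices (codons x replicates) of A-site-assigned
#'   footprint and centre-assigned mRNA fragment counts.
#' @param replicate_ids replicate labels; defaults to column names or
#'   `rep1, rep2, ...`.
#' @return a [PositionCounts-class] object.
#' @export
positionCounts <- function(gene_id, ribo, rna, replicate_ids = NULL) {
  ribo <- as.matrix(ribo); rna <- as.matrix(rna)
  if (is.null(replicate_ids))
    replicate_ids <- colnames(ribo) %||% paste0("rep", seq_len(ncol(ribo)))
  new("PositionCounts", gene_id = as.character(gene_id),
      ribo = ribo, rna = rna, replicate_ids = as.character(replicate_ids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read per-gene, per-codon counts from a TSV file
#'
#' Expected columns: `gene_id`, `codon_index` (1-based), then one column per
#' replicate per assay named `ribo_<rep>` and `rna_<rep>`. Positions absent
#' from the file are filled with zero up to the largest codon index declared
#' for the gene. Library sizes default to within-file column totals; an
#' optional override header allows analysing gene subsets with genome-wide
#' normalizers, as two comment lines listing one value per replicate in column
#' order:
#' ```
#' #library_ribo  12345  23456
#' #library_rna   34567  45678
#' ```
#'
#' @param path TSV file.
#' @return a list with elements `counts` (named list of
#'   [PositionCounts-class]) and `sizes` ([LibrarySizes-class], or NULL for an
#'   empty file — requesting sizes from an empty dataset is an error upstream).
#' @export
readPositionCounts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path)
  override <- list()
  comment <- grepl("^#", raw)
  for (ln in raw[comment]) {
    f <- strsplit(sub("^#", "", ln), "\t")[[1]]
    if (f[1] %in% c("library_ribo", "library_rna"))
      override[[f[1]]] <- as.numeric(f[-1])
  }
  body <- raw[!comment & nzchar(raw)]
  if (length(body) <= 1L)
    return(list(counts = list(), sizes = NULL))
  tab <- utils::read.delim(text = body, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "codon_index")
  if (!all(need %in% names(tab)))
    stop("counts file must have columns gene_id and codon_index")
  ribo_cols <- grep("^ribo_", names(tab), value = TRUE)
  rna_cols <- grep("^rna_", names(tab), value = TRUE)
  if (length(ribo_cols) == 0L || length(ribo_cols) != length(rna_cols))
    stop("need matching ribo_<rep> and rna_<rep> columns")
  reps <- sub("^ribo_", "", ribo_cols)
  if (!identical(reps, sub("^rna_", "", rna_cols)))
    stop("ribo and rna replicate labels must match in order")
  if (length(reps) < 2L)
    warning("fewer than 2 replicates: error-model estimation is disabled")

  cnt_cols <- c(ribo_cols, rna_cols)
  for (cc in cnt_cols) {
    v <- tab[[cc]]
    if (!is.numeric(v))
      stop(sprintf("malformed count in column %s, line %d", cc,
                   which(is.na(suppressWarnings(as.numeric(v))))[1] + 1L))
    bad <- which(!is.finite(v) | v != round(v))
    if (length(bad))
      stop(sprintf("malformed count in column %s, line %d", cc,
                   bad[1] + 1L))
    if (any(v < 0))
      stop(sprintf("negative count in column %s, line %d", cc,
                   which(v < 0)[1] + 1L))
  }
  ci <- tab$codon_index
  if (!is.numeric(ci))
    stop(sprintf("malformed codon_index at line %d",
                 which(is.na(suppressWarnings(as.numeric(ci))))[1] + 1L))
  if (any(!is.finite(ci) | ci != round(ci) | ci < 1))
    stop(sprintf("malformed codon_index at line %d",
                 which(!is.finite(ci) | ci != round(ci) | ci < 1)[1] + 1L))

  counts <- lapply(split(tab, tab$gene_id), function(g) {
    n <- max(g$codon_index)
    ribo <- matrix(0L, n, length(reps), dimnames = list(NULL, reps))
    rna <- matrix(0L, n, length(reps), dimnames = list(NULL, reps))
    ribo[g$codon_index, ] <- as.matrix(g[ribo_cols])
    rna[g$codon_index, ] <- as.matrix(g[rna_cols])
    positionCounts(g$gene_id[1], ribo, rna, reps)
  })
  # gene order as first encountered in the file
  counts <- counts[unique(tab$gene_id)]

  n_ribo <- override[["library_ribo"]] %||%
    vapply(counts[[1]]@replicate_ids,
           function(r) sum(vapply(counts, function(p) sum(p@ribo[, r]), 0)), 0)
  n_rna <- override[["library_rna"]] %||%
    vapply(counts[[1]]@replicate_ids,
           function(r) sum(vapply(counts, function(p) sum(p@rna[, r]), 0)), 0)
  names(n_ribo) <- names(n_rna) <- reps
  list(counts = counts,
       sizes = new("LibrarySizes", n_ribo = n_ribo, n_rna = n_rna))
}

#' Write position counts to the TSV format read by [readPositionCounts()]
#'
#' @param counts named list of [PositionCounts-class].
#' @param sizes optional [LibrarySizes-class] written as an override header.
#' @param path output file.
#' @export
writePositionCounts <- function(counts, path, sizes = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(sizes)) {
    writeLines(paste(c("#library_ribo", format(sizes@n_ribo, scientific = FALSE)),
                     collapse = "\t"), con)
    writeLines(paste(c("#library_rna", format(sizes@n_rna, scientific = FALSE)),
                     collapse = "\t"), con)
  }
  reps <- counts[[1]]@replicate_ids
  writeLines(paste(c("gene_id", "codon_index", paste0("ribo_", reps),
                     paste0("rna_", reps)), collapse = "\t"), con)
  for (p in counts) {
    m <- cbind(p@ribo, p@rna)
    lines <- paste(p@gene_id, seq_len(nrow(m)),
                   apply(m, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read coding sequences from a FASTA file and split them into codons
#'
#' @param path nucleotide FASTA of CDSes.
#' @return named list; each element a character vector of codons.
#' @export
readCdsFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    nm <- names(seqs)[i]
    if (nchar(s) %% 3 != 0)
      stop(sprintf("CDS length of %s (%d nt) is not divisible by 3", nm,
                   nchar(s)))
    if (grepl("[^ACGT]", s))
      stop(sprintf("non-ACGT symbol in CDS of %s", nm))
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  })
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Construct a CodonRateSet
#'
#' @param rates named numeric of length 64 (all codons, positive rates; stop
#'   codon entries act as termination rates).
#' @param fixed_codon codon whose rate anchors the scale (default "GAA").
#' @return a [CodonRateSet-class].
#' @export
codonRateSet <- function(rates, fixed_codon = "GAA") {
  new("CodonRateSet", rates = rates[allCodons()], fixed_codon = fixed_codon)
}

#' Read a 64-entry codon rate table from CSV
#'
#' Expected columns: `codon`, `rate`. Stop-codon rows act as termination
#' rates.
#'
#' @param path CSV file.
#' @param fixed_codon codon whose rate anchors the scale (default "GAA").
#' @return a [CodonRateSet-class].
#' @export
readRateTable <- function(path, fixed_codon = "GAA") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("codon", "rate") %in% names(tab)))
    stop("rate table must have columns codon, rate")
  missing <- setdiff(allCodons(), tab$codon)
  if (length(missing))
    stop("missing codons: ", paste(missing, collapse = ", "))
  if (any(!is.finite(tab$rate) | tab$rate <= 0))
    stop("non-positive rate for codon ",
         tab$codon[which(!is.finite(tab$rate) | tab$rate <= 0)[1]])
  codonRateSet(stats::setNames(tab$rate, tab$codon), fixed_codon)
}

#' Write a codon rate table as CSV
#'
#' @param rates a [CodonRateSet-class].
#' @param path output CSV.
#' @export
writeRateTable <- function(rates, path) {
  utils::write.csv(data.frame(codon = names(codonRates(rates)),
                              rate = unname(codonRates(rates))),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a GeneModel from a codon sequence and a rate set
#'
#' @param gene_id gene identifier.
#' @param codons character vector of codons (last codon the stop).
#' @param rates a [CodonRateSet-class]; per-site rates are looked up here.
#' @param k0 initiation rate (NA if not yet assigned).
#' @return a [GeneModel-class].
#' @export
geneModel <- function(gene_id, codons, rates, k0 = NA_real_) {
  site <- unname(codonRates(rates)[codons])
  if (anyNA(site)) stop("unknown codon in gene ", gene_id)
  new("GeneModel", gene_id = as.character(gene_id), codons = codons,
      k0 = as.numeric(k0), site_rates = site)
}

TREE_FORMAT_VERSION <- 1L

#' Serialize segment trees to a self-describing JSON file
#'
#' The schema is versioned; [readSegmentTrees()] refuses files written with a
#' different version. The round trip is lossless for structure, counts,
#' densities, `omega`, `mu`, `sigma` and group assignment.
#'
#' @param trees named list of [SegmentTree-class].
#' @param path output file.
#' @export
writeSegmentTrees <- function(trees, path) {
  payload <- list(
    format = "riboTASEP-segment-trees",
    version = TREE_FORMAT_VERSION,
    genes = lapply(unname(trees), function(tr) list(
      gene_id = tr@gene_id,
      replicate_ids = tr@replicate_ids,
      nodes = tr@nodes,
      R = tr@R, M = tr@M,
      d_ribo = tr@d_ribo, d_rna = tr@d_rna, omega = tr@omega,
      mu = tr@mu, sigma = tr@sigma, group = tr@group)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Read segment trees written by [writeSegmentTrees()]
#'
#' @param path JSON file.
#' @return named list of [SegmentTree-class].
#' @export
readSegmentTrees <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "riboTASEP-segment-trees"))
    stop("not a segment-tree file: ", path)
  if (!identical(as.integer(payload$version), TREE_FORMAT_VERSION))
    stop(sprintf("segment-tree format version mismatch: file has %s, expected %d",
                 payload$version, TREE_FORMAT_VERSION))
  num1 <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  trees <- lapply(payload$genes, function(rec) {
    reps <- as.character(unlist(rec$replicate_ids))
    asm <- function(rows) {
      m <- do.call(rbind, lapply(rows, function(rw)
        vapply(rw, num1, 0)))
      m <- matrix(as.numeric(m), ncol = length(reps))
      colnames(m) <- reps
      m
    }
    nodes <- as.data.frame(lapply(rec$nodes, function(col)
      as.integer(unlist(col))))
    new("SegmentTree", gene_id = rec$gene_id,
        nodes = nodes,
        R = asm(rec$R), M = asm(rec$M),
        d_ribo = asm(rec$d_ribo), d_rna = asm(rec$d_rna),
        omega = asm(rec$omega),
        mu = vapply(rec$mu, num1, 0),
        sigma = vapply(rec$sigma, num1, 0),
        group = as.integer(vapply(rec$group, num1, 0)),
        replicate_ids = reps)
  })
  names(trees) <- vapply(trees, geneId, "")
  trees
}
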