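#' Relative codon adaptiveness within synonymous families
#'
#' Normalizes any per-codon score (fitted elongation rates, tRNA adaptation
#' index weights, codon adaptation index weights) by the maximum score among
#' synonymous codons, yielding values in (0, 1] with at least one codon of
#' every amino-acid family exactly 1. Stop codons are excluded.
#'
#' @param scores named positive numeric covering all 61 sense codons (extra
#'   entries, e.g. stop codons, are ignored).
#' @return data.frame with `amino_acid`, `codon`, `value`, sorted by amino
#'   acid then descending value.
#' @export
relativeAdaptiveness <- function(scores) {
  code <- geneticCode()
  sense <- names(code)[code != "*"]
  missing <- setdiff(sense, names(scores))
  if (length(missing))
    stop("missing sense codons: ", paste(missing, collapse = ", "))
  s <- scores[sense]
  if (any(!is.finite(s) | s <= 0)) stop("scores must be positive")
  aa <- code[sense]
  out <- do.call(rbind, lapply(split(seq_along(sense), aa), function(i)
    data.frame(amino_acid = unname(aa[i][1]), codon = sense[i],
               value = unname(s[i] / max(s[i])))))
  out <- out[order(out$amino_acid, -out$value), ]
  rownames(out) <- NULL
  out
}

#' Compare the optimal codons of two adaptiveness tables
#'
#' Lists, per amino acid, the codon(s) with maximal relative adaptiveness in
#' each table and whether the two tables agree. Ties are reported explicitly
#' rather than broken.
#'
#' @param tableA,tableB data.frames from [relativeAdaptiveness()].
#' @return data.frame with `amino_acid`, `optimal_a`, `optimal_b` (ties
#'   joined with "/"), `agree`; single-codon families always agree.
#' @export
optimalCodonAgreement <- function(tableA, tableB) {
  top <- function(tab, aa) {
    t <- tab[tab$amino_acid == aa, ]
    sort(t$codon[t$value >= max(t$value) - 1e-12])
  }
  aas <- sort(unique(tableA$amino_acid))
  if (!setequal(aas, unique(tableB$amino_acid)))
    stop("tables cover different amino acids")
  rows <- lapply(aas, function(aa) {
    a <- top(tableA, aa); b <- top(tableB, aa)
    data.frame(amino_acid = aa,
               optimal_a = paste(a, collapse = "/"),
               optimal_b = paste(b, collapse = "/"),
               agree = length(intersect(a, b)) > 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
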