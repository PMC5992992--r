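#' Escape-behaviour contingency table
#'
#' Counts of zebrafish larvae classified as `normal`, `mild` or `severe`
#' escape responders per experimental condition.
#'
#' @param counts numeric matrix or data.frame with columns `normal`, `mild`,
#'   `severe` and one row per condition.
#' @param conditions condition labels; defaults to the row names of
#'   `counts`.
#' @return object of class `escape_table` with fields `conditions`, `counts`
#'   (integer matrix) and `totals`.
#' @export
escape_table <- function(counts, conditions = rownames(counts)) {
  counts <- as.matrix(counts[, c("normal", "mild", "severe"), drop = FALSE])
  if (any(counts < 0) || any(counts != round(counts)))
    stop_config("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (is.null(conditions)) conditions <- paste0("condition_", seq_len(nrow(counts)))
  rownames(counts) <- conditions
  structure(list(conditions = conditions, counts = counts,
                 totals = rowSums(counts)),
            class = "escape_table")
}

#' @export
print.escape_table <- function(x, ...) {
  cat("<escape_table>\n")
  print(cbind(x$counts, total = x$totals))
  invisible(x)
}

#' Read an escape table from CSV
#'
#' Expected columns: `condition`, `normal`, `mild`, `severe`.
#'
#' @param path CSV path.
#' @return an [escape_table()].
#' @export
read_escape_table <- function(path) {
  dt <- as.data.frame(data.table::fread(path))
  escape_table(dt[, c("normal", "mild", "severe")],
               conditions = as.character(dt$condition))
}

#' Packaged zebrafish escape-behaviour counts
#'
#' The four-condition fixture shipped with the package (dhx37 morpholino
#' alone, + control RNA, + wild-type GlyR alpha1 RNA, + GlyR alpha1 Q177K
#' RNA; row totals 38, 31, 79, 63).
#'
#' @return an [escape_table()].
#' @export
zebrafish_escape_counts <- function() {
  read_escape_table(system.file("extdata", "zebrafish_escape_counts.csv",
                                package = "glyrfluct", mustWork = TRUE))
}

#' Integer class percentages by largest-remainder rounding
#'
#' Percentages per condition computed with the largest-remainder (Hamilton)
#' method: floor all percentages, then distribute the remaining points by
#' largest fractional part, so each row sums to exactly 100. (Plain
#' nearest-integer rounding does not generally sum to 100.)
#'
#' @param table an [escape_table()].
#' @return integer matrix of percentages, rows summing to 100.
#' @export
class_percentages <- function(table) {
  if (any(table$totals <= 0)) stop_config("all row totals must be > 0")
  out <- t(vapply(seq_along(table$totals), function(i) {
    largest_remainder(100 * table$counts[i, ] / table$totals[i])
  }, integer(ncol(table$counts))))
  dimnames(out) <- dimnames(table$counts)
  out
}

## Hamilton apportionment of `target` total over real-valued shares
largest_remainder <- function(shares, target = 100L) {
  fl <- floor(shares)
  rem <- target - sum(fl)
  if (rem > 0) {
    give <- order(shares - fl, decreasing = TRUE)[seq_len(rem)]
    fl[give] <- fl[give] + 1
  }
  as.integer(fl)
}

## Pearson chi-square on a 2x2 table, no continuity correction:
## chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
chi_square_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(list(statistic = NA_real_, p = NA_real_))
  stat <- n * (a * d - b * c)^2 / denom
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Map p-values to significance stars
#'
#' `***` for p < 0.001, `*` for p < 0.05, `n.s.` otherwise (the two-level
#' star convention of behavioural contingency tables).
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***", ifelse(p < 0.05, "*", "n.s.")))
}

#' Pairwise chi-square tests between conditions
#'
#' For every pair of conditions, the chosen category is tested against all
#' other categories in a 2x2 table by Pearson chi-square with 1 df and no
#' continuity correction (`mode = "category"`), or the full 1 x 3
#' distributions are compared (2 df, `mode = "full"`). Pairs with an
#' expected cell below 1 carry a warning flag.
#'
#' @param table an [escape_table()].
#' @param category `"normal"`, `"mild"` or `"severe"` (ignored for
#'   `mode = "full"`).
#' @param mode `"category"` (default, per-category 2x2 framing) or
#'   `"full"`.
#' @return list of class `pairwise_chisq` with matrices `statistic`, `p`,
#'   `stars` and logical `warning_flag`, all `conditions x conditions`.
#' @export
pairwise_chi_square <- function(table, category = c("normal", "mild",
                                                    "severe"),
                                mode = c("category", "full")) {
  mode <- match.arg(mode)
  category <- match.arg(category)
  k <- length(table$conditions)
  if (k < 2L) stop_config("need >= 2 conditions")
  stat <- p <- matrix(NA_real_, k, k,
                      dimnames = list(table$conditions, table$conditions))
  warn <- matrix(FALSE, k, k,
                 dimnames = list(table$conditions, table$conditions))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (mode == "category") {
      a <- table$counts[i, category]; b <- table$totals[i] - a
      cc <- table$counts[j, category]; d <- table$totals[j] - cc
      res <- chi_square_2x2(a, b, cc, d)
      n <- a + b + cc + d
      expected <- outer(c(a + b, cc + d), c(a + cc, b + d)) / n
    } else {
      m <- table$counts[c(i, j), , drop = FALSE]
      expected <- outer(rowSums(m), colSums(m)) / sum(m)
      stat_full <- sum((m - expected)^2 / expected)
      res <- list(statistic = stat_full,
                  p = pchisq(stat_full, df = (ncol(m) - 1),
                             lower.tail = FALSE))
    }
    stat[i, j] <- stat[j, i] <- res$statistic
    p[i, j] <- p[j, i] <- res$p
    warn[i, j] <- warn[j, i] <- any(expected < 1)
  }
  structure(list(statistic = stat, p = p,
                 stars = structure(significance_stars(p), dim = dim(p),
                                   dimnames = dimnames(p)),
                 warning_flag = warn, category = category, mode = mode),
            class = "pairwise_chisq")
}

#' @export
print.pairwise_chisq <- function(x, ...) {
  cat(sprintf("<pairwise_chisq> mode=%s category=%s\n", x$mode, x$category))
  print(x$stars, quote = FALSE)
  invisible(x)
}

#' In-silico restriction digest
#'
#' Locates all (possibly overlapping) occurrences of a recognition sequence
#' and cuts at a fixed offset within each site (default `TG^CA`, i.e. the
#' blunt cutter HpyCH4V, whose site in wild-type Glra1 exon 6 is destroyed
#' by the startle-disease c.C613A substitution). Used for digest-based
#' genotyping: a sequence that is cut is called wild-type-like.
#'
#' @param sequence nucleotide string over A/C/G/T (case-insensitive), or a
#'   `Biostrings::DNAString`.
#' @param recognition recognition sequence, default `"TGCA"`.
#' @param cut_offset 0-based offset of the cut within the site, default 2
#'   (between positions 2 and 3: TG^CA).
#' @return object of class `digest_result`: `fragment_lengths` (bp, 5' to
#'   3'), `cut_positions` (0-based offsets into the sequence),
#'   `genotype_call` (`"cut"` or `"uncut"`), `sequence_length`.
#' @export
insilico_digest <- function(sequence, recognition = "TGCA",
                            cut_offset = 2L) {
  if (inherits(sequence, "DNAString") || inherits(sequence, "XString"))
    sequence <- as.character(sequence)
  seq <- toupper(sequence)
  if (!nzchar(seq)) stop_config("empty sequence")
  if (grepl("[^ACGT]", seq))
    stop_config("sequence contains non-nucleotide characters")
  recognition <- toupper(recognition)
  n <- nchar(seq)
  hits <- gregexpr(paste0("(?=", recognition, ")"), seq, perl = TRUE)[[1]]
  starts0 <- if (hits[1] == -1) integer() else as.integer(hits) - 1L
  cuts <- starts0 + cut_offset
  cuts <- sort(unique(cuts[cuts > 0 & cuts < n])) # interior cuts only
  bounds <- c(0L, cuts, n)
  structure(list(fragment_lengths = as.integer(diff(bounds)),
                 cut_positions = as.integer(cuts),
                 genotype_call = if (length(cuts)) "cut" else "uncut",
                 sequence_length = n,
                 recognition = recognition),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest_result> %s site %s: %d cut(s), fragments [%s] bp\n",
              x$genotype_call, x$recognition, length(x$cut_positions),
              paste(x$fragment_lengths, collapse = ", ")))
  invisible(x)
}

#' Read the first sequence from a FASTA file or pass a raw string through
#'
#' @param x path to a FASTA file, or a nucleotide string.
#' @return upper-case nucleotide string.
#' @export
read_sequence <- function(x) {
  if (file.exists(x)) {
    set <- Biostrings::readDNAStringSet(x)
    return(toupper(as.character(set[[1]])))
  }
  toupper(x)
}

#' Reverse complement of a nucleotide string
#' @param sequence nucleotide string.
#' @return reverse-complemented string.
#' @export
reverse_complement <- function(sequence)
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(sequence))))
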