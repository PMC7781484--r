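# Position weight matrices: Dirichlet sampling, LLR scoring, promoter
# scanning on both strands.

DNA_BASES <- c("A", "C", "G", "T")

#' Sample a random position weight matrix
#'
#' Each PWM column is drawn from a symmetric 4-dimensional Dirichlet
#' distribution. The per-position concentration parameters default to
#' `c(0.4, 0.3, 0.2, 0.1, 0.1, 0.2, 0.3, 0.4)`: lower alphas in the middle
#' produce sharper (more informative) core positions and more degenerate
#' extremes, as in PWMs derived from PBM or SELEX experiments. Raw Dirichlet
#' draws can contain zeros, which would give infinitely negative
#' log-likelihood-ratio (LLR) scores, so entries are floored at `prob_floor`
#' and the column renormalized. A PWM whose consensus LLR is not positive
#' would make the site-retention threshold meaningless and is resampled.
#'
#' @param L motif length in bases.
#' @param alphas per-position Dirichlet concentration parameters (length `L`).
#' @param prob_floor minimum nucleotide probability after flooring.
#' @param threshold_frac binding sites are retained when their LLR is at
#'   least this fraction of the consensus LLR.
#' @param tf_id optional integer identity attached to the PWM.
#' @return an object of class `grn_pwm` with elements `probs` (4 x L,
#'   rows A,C,G,T), `logodds` (log2 probability over the uniform 0.25
#'   background), `L`, `background`, `llr_max` (consensus LLR, bits),
#'   `min_llr` (= `threshold_frac * llr_max`), `consensus`, `tf_id`.
#' @export
#' @examples
#' set.seed(1)
#' pwm <- sample_pwm()
#' colSums(pwm$probs)  # all 1
sample_pwm <- function(L = 8L,
                       alphas = c(0.4, 0.3, 0.2, 0.1, 0.1, 0.2, 0.3, 0.4),
                       prob_floor = 1e-4, threshold_frac = 0.7,
                       tf_id = NA_integer_) {
  if (length(alphas) != L) stop("length(alphas) must equal L")
  if (any(alphas <= 0)) stop("Dirichlet alphas must be positive")
  repeat {
    probs <- vapply(alphas, function(a) {
      x <- rgamma(4L, shape = a, rate = 1)
      # a gamma draw can underflow to all-zero at tiny shape; retry
      while (sum(x) == 0) x <- rgamma(4L, shape = a, rate = 1)
      p <- x / sum(x)
      p <- pmax(p, prob_floor)
      p / sum(p)
    }, numeric(4L))
    dimnames(probs) <- list(DNA_BASES, NULL)
    pwm <- new_pwm(probs, threshold_frac, tf_id)
    if (pwm$llr_max > 0) return(pwm)
  }
}

# Construct a grn_pwm from a 4 x L probability matrix.
new_pwm <- function(probs, threshold_frac = 0.7, tf_id = NA_integer_) {
  if (nrow(probs) != 4L) stop("PWM probability matrix must have 4 rows")
  if (any(abs(colSums(probs) - 1) > 1e-9))
    stop("PWM columns must sum to 1")
  logodds <- log2(probs / 0.25)
  llr_max <- sum(apply(logodds, 2, max))
  cons <- paste(DNA_BASES[apply(probs, 2, which.max)], collapse = "")
  structure(list(probs = probs, logodds = logodds, L = ncol(probs),
                 background = 0.25, llr_max = llr_max,
                 min_llr = threshold_frac * llr_max,
                 threshold_frac = threshold_frac,
                 consensus = cons, tf_id = tf_id),
            class = "grn_pwm")
}

#' @export
print.grn_pwm <- function(x, ...) {
  cat("grn_pwm L=", x$L, " consensus=", x$consensus,
      " llr_max=", format(x$llr_max, digits = 4),
      " min_llr=", format(x$min_llr, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Sample one PWM per transcription factor
#'
#' @param n_tfs number of TFs.
#' @param ... passed to [sample_pwm()].
#' @return list of `grn_pwm`, one per TF, with `tf_id` set to 1..n_tfs.
#' @export
sample_pwm_set <- function(n_tfs, ...) {
  lapply(seq_len(n_tfs), function(h) sample_pwm(tf_id = h, ...))
}

#' Log-likelihood-ratio score of a sequence window under a PWM
#'
#' The LLR of a window is the sum over positions of
#' `log2(p(base, position) / 0.25)`, i.e. the log2 odds of the window under
#' the PWM relative to a uniform background.
#'
#' @param window a character string over A,C,G,T of length `pwm$L`.
#' @param pwm a `grn_pwm`.
#' @return the score in bits.
#' @export
#' @examples
#' uniform <- grnevolve:::new_pwm(matrix(0.25, 4, 8,
#'   dimnames = list(c("A","C","G","T"), NULL)))
#' llr_score(paste(rep("A", 8), collapse = ""), uniform)  # 0
llr_score <- function(window, pwm) {
  chars <- strsplit(toupper(window), "")[[1]]
  if (length(chars) != pwm$L)
    stop("window length ", length(chars), " does not match PWM length ", pwm$L)
  idx <- match(chars, DNA_BASES)
  if (anyNA(idx))
    stop("invalid character '", chars[which(is.na(idx))[1]],
         "' at position ", which(is.na(idx))[1], " (alphabet is A,C,G,T)")
  sum(pwm$logodds[cbind(idx, seq_len(pwm$L))])
}

#' Consensus LLR of a PWM
#'
#' The LLR of the strongest possible site: the column-wise most probable
#' base at each position (ties broken in A < C < G < T order, which does not
#' affect the score).
#'
#' @param pwm a `grn_pwm`.
#' @return the consensus score in bits (equals `pwm$llr_max`).
#' @export
consensus_llr <- function(pwm) {
  sum(apply(pwm$logodds, 2, max))
}

#' Scan a promoter for binding sites of one TF
#'
#' Every window of length `pwm$L` is scored on the forward strand and on the
#' reverse complement; windows whose LLR reaches the PWM's retention
#' threshold (`min_llr`, by default 70% of the consensus LLR) are returned
#' as binding sites. Overlapping sites are all retained: sites do not
#' compete for sequence. Reverse-strand sites are reported by the 0-based
#' start of their forward-strand window, so the site occupies
#' `[position, position + L)` regardless of strand.
#'
#' @param seq promoter sequence (character string over A,C,G,T).
#' @param pwm a `grn_pwm`.
#' @param tf_id TF identity recorded in the result (defaults to
#'   `pwm$tf_id`).
#' @param gene_id optional gene identity recorded in the result.
#' @param llr_scale multiplier applied to the bits-valued LLR deficit before
#'   exponentiation when computing the concentration-free statistical weight
#'   `q_base = exp(llr_scale * (llr - llr_max))`; 1 exponentiates the bits
#'   value directly, `log(2)` converts to natural log units first.
#' @return a data.frame with columns `gene_id`, `tf_id`, `position`
#'   (0-based window start), `strand` ("+"/"-"), `llr` (bits), `q_base`.
#'   Sequences shorter than the PWM give an empty result with a warning.
#' @export
scan_promoter <- function(seq, pwm, tf_id = pwm$tf_id, gene_id = NA_integer_,
                          llr_scale = 1) {
  if (nchar(seq) < pwm$L) {
    warning("sequence shorter than PWM length (", nchar(seq), " < ", pwm$L,
            "); no sites")
    return(empty_sites())
  }
  df <- cpp_scan_promoter(toupper(seq), pwm$logodds, pwm$llr_max, pwm$min_llr,
                          llr_scale)
  data.frame(gene_id = rep(as.integer(gene_id), nrow(df)),
             tf_id = rep(as.integer(tf_id), nrow(df)),
             position = df$position,
             strand = c("+", "-")[df$strand + 1L],
             llr = df$llr, q_base = df$q_base,
             stringsAsFactors = FALSE)
}

empty_sites <- function() {
  data.frame(gene_id = integer(0), tf_id = integer(0), position = integer(0),
              strand = character(0), llr = numeric(0), q_base = numeric(0),
              stringsAsFactors = FALSE)
}

#' Reverse complement of a DNA string
#' @param seq character string over A,C,G,T.
#' @return the reverse complement string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read and write PWMs in MEME minimal motif format
#'
#' The probability matrices of a PWM set are written as a MEME minimal
#' format file (one `MOTIF` block per TF with a letter-probability matrix);
#' `read_meme()` parses such a file back into `grn_pwm` objects.
#'
#' @param pwms list of `grn_pwm`.
#' @param path output file.
#' @param threshold_frac retention threshold fraction applied to PWMs read
#'   back from a file.
#' @return `write_meme()`: the path, invisibly. `read_meme()`: a list of
#'   `grn_pwm`.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (i in seq_along(pwms)) {
    p <- pwms[[i]]
    id <- if (is.na(p$tf_id)) i else p$tf_id
    writeLines(sprintf("MOTIF tf%d", id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", p$L), con)
    writeLines(apply(p$probs, 2, function(col)
      paste(sprintf("%.8f", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_meme
#' @export
read_meme <- function(path, threshold_frac = 0.7) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  if (length(starts) == 0L) stop("no MOTIF blocks found in ", path)
  lapply(seq_along(starts), function(k) {
    i <- starts[k]
    name <- sub("^MOTIF\\s+(\\S+).*$", "\\1", lines[i])
    hdr <- i + 1L
    while (hdr <= length(lines) && !grepl("^letter-probability matrix", lines[hdr]))
      hdr <- hdr + 1L
    if (hdr > length(lines))
      stop("MEME parse error at line ", i, ": no letter-probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4L)))
    probs <- t(mat)
    dimnames(probs) <- list(DNA_BASES, NULL)
    # renormalize against truncation in the text representation
    probs <- sweep(probs, 2, colSums(probs), "/")
    tf_id <- suppressWarnings(as.integer(sub("^tf", "", name)))
    new_pwm(probs, threshold_frac = threshold_frac, tf_id = tf_id)
  })
}
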