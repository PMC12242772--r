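#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   matchPattern readDNAStringSet writeXStringSet
#' @importFrom BiocGenerics start end width strand
#' @importFrom stats rnorm rpois runif median setNames
NULL

# Coerce a sequence argument to a single DNAString, enforcing the
# A/C/G/T/N alphabet (IUPAC ambiguity codes other than N are rejected:
# tract purity is defined over unambiguous bases).
.asDNA <- function(seq, what = "sequence") {
    if (is(seq, "DNAString")) s <- seq
    else if (is.character(seq) && length(seq) == 1L) {
        s <- tryCatch(DNAString(toupper(seq)),
                      error = function(e) stop(sprintf(
                          "%s contains non-DNA characters: %s",
                          what, conditionMessage(e)), call. = FALSE))
    } else stop(sprintf("%s must be a DNAString or a single character string", what),
                call. = FALSE)
    lets <- Biostrings::uniqueLetters(s)
    bad <- setdiff(lets, c("A", "C", "G", "T", "N"))
    if (length(bad))
        stop(sprintf("%s contains characters other than A/C/G/T/N: %s",
                     what, paste(bad, collapse = "")), call. = FALSE)
    s
}

# SAM FLAG bit helpers -------------------------------------------------------

.FLAG_PAIRED      <- 0x1
.FLAG_PROPER_PAIR <- 0x2
.FLAG_UNMAPPED    <- 0x4
.FLAG_MREVERSE    <- 0x20
.FLAG_REVERSE     <- 0x10
.FLAG_READ1       <- 0x40
.FLAG_READ2       <- 0x80
.FLAG_SECONDARY   <- 0x100
.FLAG_DUP         <- 0x400
.FLAG_SUPPL       <- 0x800

#' Decode SAM FLAG bits
#'
#' @param flag integer vector of SAM FLAG values.
#' @return A logical matrix with one row per flag and columns `paired`,
#'   `proper_pair`, `reverse_strand`, `first_in_pair`, `secondary`,
#'   `duplicate`, `supplementary`, `primary` (primary = neither secondary
#'   nor supplementary).
#' @examples
#' flagBits(c(0L, 16L, 99L, 2048L))
#' @export
flagBits <- function(flag) {
    flag <- as.integer(flag)
    m <- cbind(
        paired         = bitwAnd(flag, .FLAG_PAIRED) != 0L,
        proper_pair    = bitwAnd(flag, .FLAG_PROPER_PAIR) != 0L,
        reverse_strand = bitwAnd(flag, .FLAG_REVERSE) != 0L,
        first_in_pair  = bitwAnd(flag, .FLAG_READ1) != 0L,
        secondary      = bitwAnd(flag, .FLAG_SECONDARY) != 0L,
        duplicate      = bitwAnd(flag, .FLAG_DUP) != 0L,
        supplementary  = bitwAnd(flag, .FLAG_SUPPL) != 0L
    )
    cbind(m, primary = !m[, "secondary"] & !m[, "supplementary"])
}

# An empty alignment table with the canonical column set.
.emptyAlignments <- function() {
    data.frame(read_id = character(), seq_id = character(),
               start = integer(), end = integer(), strand = character(),
               mapq = integer(), flag = integer(),
               stringsAsFactors = FALSE)
}

# Validate/standardize an alignment data.frame (1-based closed coordinates,
# matching SAM POS / reference span).
.checkAlignments <- function(aln) {
    need <- c("read_id", "seq_id", "start", "end", "mapq", "flag")
    missing <- setdiff(need, colnames(aln))
    if (length(missing))
        stop("alignment table lacks columns: ", paste(missing, collapse = ", "),
             call. = FALSE)
    if (!"strand" %in% colnames(aln))
        aln$strand <- ifelse(bitwAnd(as.integer(aln$flag), .FLAG_REVERSE) != 0L,
                             "-", "+")
    if (any(aln$start > aln$end))
        stop("alignment records with start > end", call. = FALSE)
    aln
}

# running median with odd window, endpoints copied from the nearest
# computed value (endrule "constant")
.runningMedian <- function(x, k) {
    k <- max(1L, as.integer(k))
    if (k %% 2L == 0L) k <- k + 1L
    if (k >= length(x)) k <- max(1L, length(x) - (1L - length(x) %% 2L))
    if (k <= 1L) return(x)
    as.numeric(stats::runmed(x, k, endrule = "constant"))
}
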