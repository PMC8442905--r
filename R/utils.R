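# Internal argument checks shared across modules.

.check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %s", name, format(min)), call. = FALSE)
  }
  as.integer(x)
}

.check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi), call. = FALSE)
  }
  as.numeric(x)
}

.check_fraction <- function(x, name) .check_number(x, name, 0, 1)

# Deterministic per-task seed derivation, kept within 32-bit integer range.
.derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2000L + as.integer(offset) %% 2000L
}

.clip01 <- function(x, eps = 0) pmax(pmin(x, 1 - eps), eps)  # x first: keeps dims

# id string for a window/region
.region_id <- function(chrom, start, end) sprintf("%s:%d-%d", chrom, start, end)

# parse "chr:start-end" ids back to a data.table (0-based half-open)
.parse_region_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([0-9]+)-([0-9]+)$", id))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed region id: ", id[bad][1], call. = FALSE)
  data.table::data.table(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end   = as.integer(vapply(m, `[`, "", 4L))
  )
}

# GRanges from 0-based half-open coordinates
.gr0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1, end = end))
}

.gr_from_ids <- function(ids) {
  bed <- .parse_region_id(ids)
  gr <- .gr0(bed$chrom, bed$start, bed$end)
  names(gr) <- ids
  gr
}
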