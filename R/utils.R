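#' @keywords internal
"_PACKAGE"

# round-half-up: round(2.5) in base R is banker's rounding; grid-dimension and
# rank arithmetic here needs the conventional half-up rule.
round_half_up <- function(x) floor(x + 0.5)

# Split a ";"-joined accession field into a deduplicated character set.
split_accessions <- function(x) {
  if (length(x) == 0 || is.na(x) || !nzchar(x)) return(character(0))
  unique(trimws(strsplit(x, ";", fixed = TRUE)[[1]]))
}

join_accessions <- function(x) paste(unique(x), collapse = ";")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
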