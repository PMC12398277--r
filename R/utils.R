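# Internal helpers shared across modules.

# INFO fields are stored as the raw VCF semicolon string ("K=V;FLAG;...").
info_get <- function(info, key) {
  out <- rep(NA_character_, length(info))
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regexpr(pat, info, perl = TRUE)
  hit <- m > 0 & !is.na(info)
  if (any(hit)) {
    out[hit] <- sub(paste0(".*(?:^|;)", key, "=([^;]*).*"), "\\1",
                    info[hit], perl = TRUE)
  }
  out
}

info_set <- function(info, key, value) {
  info[is.na(info) | info == "." | info == ""] <- NA_character_
  pat <- paste0("(?:^|;)", key, "=[^;]*")
  has <- !is.na(info) & grepl(pat, info, perl = TRUE)
  info[has] <- sub(pat, paste0(";", key, "=", value[has]), info[has],
                   perl = TRUE)
  info[has] <- sub("^;", "", info[has])
  add <- !has
  info[add] <- ifelse(is.na(info[add]),
                      paste0(key, "=", value[add]),
                      paste0(info[add], ";", key, "=", value[add]))
  info
}

# genotype missing = no called allele for that sample (./. or .)
gt_missing <- function(g) apply(is.na(g), 1L, all)

# alt-allele dosage per sample; NA when the genotype is missing
gt_dosage <- function(g) {
  d <- rowSums(g == 1L, na.rm = TRUE)
  d[gt_missing(g)] <- NA_integer_
  d
}

assert_columns <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss) > 0) {
    abort(sprintf("%s must have column(s): %s", what,
                  paste(miss, collapse = ", ")))
  }
  invisible(x)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == trunc(x)
}
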