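#' Read and write the shared tabular dialects
#'
#' The concentrations CSV has columns `site`, `analyte`, `value` (ug/m3 for
#' air species, ug/g crt for biomarker summaries); the urine CSV has columns
#' `participant_id`, `site`, `sex`, `smoker`, `age_group`, `analyte`,
#' `raw_ugL`, `creatinine_gL`. Readers validate the column set so that every
#' file the generator writes parses back losslessly.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return The data frame (readers), or `path` invisibly (writers).
#' @export
read_concentrations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "analyte", "value")
  if (!all(need %in% names(df))) {
    stop("concentrations file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_concentrations
#' @export
write_concentrations <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_concentrations
#' @export
read_urine <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "site", "sex", "smoker", "age_group",
            "analyte", "raw_ugL", "creatinine_gL")
  if (!all(need %in% names(df))) {
    stop("urine file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$smoker <- as.logical(df$smoker)
  df
}

#' @rdname read_concentrations
#' @export
write_urine <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

# FNV-1a 64-bit hash over a string, returned as 16 hex digits. Used for the
# run-manifest config hash (deterministic for identical content).
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  # 64-bit arithmetic via two 32-bit halves to stay in double precision
  lo <- 0x84222325; hi <- 0xcbf29ce4
  p_lo <- 0x1b3; p_hi <- 0x100  # FNV prime 0x100000001b3
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep arithmetic in doubles
    low_byte <- lo %% 256
    lo <- lo - low_byte + bitwXor(as.integer(low_byte), as.integer(b))
    # (hi,lo) * (p_hi,p_lo) mod 2^64, 16-bit limbs to avoid overflow
    a <- c(lo %% 65536, lo %/% 65536, hi %% 65536, hi %/% 65536)
    m <- c(p_lo %% 65536, p_lo %/% 65536, p_hi %% 65536, p_hi %/% 65536)
    r <- numeric(4); carry <- 0
    for (i in 1:4) {
      acc <- carry
      for (j in 1:i) acc <- acc + a[j] * m[i - j + 1]
      r[i] <- acc %% 65536
      carry <- acc %/% 65536
    }
    lo <- r[1] + r[2] * 65536
    hi <- r[3] + r[4] * 65536
  }
  to_hex <- function(v) {
    paste(format.hexmode(c(v %/% 65536, v %% 65536), width = 4),
          collapse = "")
  }
  paste0(to_hex(hi), to_hex(lo))
}

config_hash <- function(config) {
  fnv1a_hash(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE))
}
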