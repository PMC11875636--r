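#' @keywords internal
"_PACKAGE"

# Deterministic seed splitter: one user-facing seed expands into independent
# per-stage seeds so that stages can be re-run in isolation and still
# reproduce a full pipeline run. FNV-1a style hash folded into [1, 2^31 - 2].
derive_seed <- function(seed, ...) {
  tags <- paste(c(seed, list(...)), collapse = "/")
  bytes <- utf8ToInt(tags)
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte; keeps everything in double-safe range
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), as.integer(b))
    # 32-bit multiply by FNV prime 16777619 without overflow (split in halves)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  as.integer(h %% 2147483646) + 1L
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

bfn_log <- function(level, fmt, ...) {
  if (isTRUE(getOption("bandfocus.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(fmt, ...) {
  stop(structure(class = c("bfn_config_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
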