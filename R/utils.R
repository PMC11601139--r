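#' @keywords internal
"_PACKAGE"

# Derive a stage-specific RNG seed from a master seed. Kept below 2^31 so the
# result is always a valid R integer.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1)
  as.integer((as.numeric(master) * 7919 + 104729 * stage) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_adr <- function(msg, class) {
  stop(structure(class = c(class, "adr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

warn_adr <- function(msg, class) {
  warning(structure(class = c(class, "adr_warning", "warning", "condition"),
                    list(message = msg, call = sys.call(-1))))
}

is_binary01 <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1))
}

sigmoid <- function(x) 1 / (1 + exp(-x))
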