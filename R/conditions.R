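# Typed conditions.  Every error raised by this package carries class
# "bbi_error" plus one refining class so callers (and the CLI layer, which
# maps them to exit codes) can dispatch without string matching.

bbiStop <- function(msg, class, call = sys.call(-1), ...) {
  stop(structure(
    class = c(class, "bbi_error", "error", "condition"),
    list(message = msg, call = call, ...)
  ))
}

# malformed text input; carries `line` when known
bbiParseError <- function(msg, line = NA_integer_) {
  if (!is.na(line)) msg <- sprintf("line %d: %s", line, msg)
  bbiStop(msg, "bbi_parse_error", line = line)
}

# well-formed input that violates a contract (unsorted, overlap, bounds...)
bbiValidationError <- function(msg, line = NA_integer_) {
  if (!is.na(line)) msg <- sprintf("line %d: %s", line, msg)
  bbiStop(msg, "bbi_validation_error", line = line)
}

# structurally broken binary file
bbiFormatError <- function(msg, offset = NA_real_) {
  if (!is.na(offset)) msg <- sprintf("%s (at file offset %.0f)", msg, offset)
  bbiStop(msg, "bbi_format_error", offset = offset)
}

# operation applied to the wrong kind of BBI file
bbiKindError <- function(msg) bbiStop(msg, "bbi_kind_error")

# a name (chromosome, zoom level) not present in the file
bbiNotFoundError <- function(msg) bbiStop(msg, "bbi_notfound_error")
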