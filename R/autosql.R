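# autoSql: the schema definition language BigBed files embed to describe
# their columns.  Grammar handled here:
#
#   table <name>
#   "<table comment>"
#   (
#   <type tokens> <name> ; "<field comment>"
#   ...
#   )
#
# Type tokens are kept verbatim (no type checking); comments may contain
# any character except an unescaped double quote.

#' Parse an autoSql schema
#'
#' @param text schema text (a single string, possibly multi-line).
#' @return an [AutoSql-class] object.
#' @examples
#' sch <- parseAutoSql(autoSqlForBed(6))
#' sch@fields$name
#' @export
parseAutoSql <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n <- nchar(text)
  pos <- 1L  # scanner offset, 1-based; reported in errors

  peekRest <- function() substr(text, pos, n)
  skipWs <- function() {
    m <- regexpr("^[ \t\r\n]+", peekRest())
    if (m == 1L) pos <<- pos + attr(m, "match.length")
  }
  expectWord <- function() {
    skipWs()
    m <- regexpr("^[^ \t\r\n();\"]+", peekRest())
    if (m != 1L)
      bbiParseError(sprintf("autoSql: expected a word at offset %d", pos))
    w <- substr(text, pos, pos + attr(m, "match.length") - 1L)
    pos <<- pos + attr(m, "match.length")
    w
  }
  expectQuoted <- function() {
    skipWs()
    if (substr(text, pos, pos) != "\"")
      bbiParseError(sprintf("autoSql: expected '\"' at offset %d", pos))
    close <- regexpr("\"", substr(text, pos + 1L, n), fixed = TRUE)
    if (close < 0)
      bbiParseError(sprintf("autoSql: unbalanced quote opened at offset %d",
                            pos))
    s <- substr(text, pos + 1L, pos + close - 1L)
    pos <<- pos + close + 1L
    s
  }
  expectChar <- function(ch) {
    skipWs()
    if (substr(text, pos, pos) != ch)
      bbiParseError(sprintf("autoSql: expected '%s' at offset %d", ch, pos))
    pos <<- pos + 1L
  }

  kw <- expectWord()
  if (kw != "table")
    bbiParseError(sprintf(
      "autoSql: expected keyword 'table', got '%s' at offset %d", kw, pos))
  tableName <- expectWord()
  tableComment <- expectQuoted()
  expectChar("(")
  types <- character(); fnames <- character(); comments <- character()
  repeat {
    skipWs()
    if (pos > n)
      bbiParseError("autoSql: unbalanced '(' — missing closing ')'")
    if (substr(text, pos, pos) == ")") { pos <- pos + 1L; break }
    toks <- character()
    repeat {
      toks <- c(toks, expectWord())
      skipWs()
      if (substr(text, pos, pos) == ";") { pos <- pos + 1L; break }
      if (pos > n)
        bbiParseError("autoSql: field declaration missing ';'")
    }
    if (length(toks) < 2L)
      bbiParseError(sprintf(
        "autoSql: field needs a type and a name near offset %d", pos))
    types <- c(types, paste(toks[-length(toks)], collapse = " "))
    fnames <- c(fnames, toks[length(toks)])
    skipWs()
    comments <- c(comments,
                  if (substr(text, pos, pos) == "\"") expectQuoted() else "")
  }
  new("AutoSql", name = tableName, comment = tableComment,
      fields = data.frame(type = types, name = fnames, comment = comments))
}

#' Render an AutoSql schema back to text
#'
#' `parseAutoSql(formatAutoSql(x))` reparses to an equal schema.
#'
#' @param x an [AutoSql-class].
#' @return schema text (single string).
#' @export
formatAutoSql <- function(x) {
  stopifnot(is(x, "AutoSql"))
  paste0(
    "table ", x@name, "\n\"", x@comment, "\"\n(\n",
    paste0("    ", x@fields$type, " ", x@fields$name, " ;\t\"",
           x@fields$comment, "\"\n", collapse = ""),
    ")\n")
}

# canonical column definitions of the standard BED fields
.bedStdFields <- data.frame(
  type = c("string", "uint", "uint", "string", "uint", "char[1]",
           "uint", "uint", "uint", "int", "int[blockCount]",
           "int[blockCount]"),
  name = c("chrom", "chromStart", "chromEnd", "name", "score", "strand",
           "thickStart", "thickEnd", "reserved", "blockCount",
           "blockSizes", "chromStarts"),
  comment = c("Reference sequence chromosome or scaffold",
              "Start position in chromosome",
              "End position in chromosome",
              "Name of item", "Score (0-1000)", "+ or - for strand",
              "Start of where display should be thick",
              "End of where display should be thick",
              "Used as itemRgb", "Number of blocks",
              "Comma separated list of block sizes",
              "Start positions relative to chromStart"))

#' Stock autoSql schema for a plain bedN(+P) layout
#'
#' Builds a schema with the standard definitions of the first
#' `definedFields` BED columns and generic string columns for any extras.
#'
#' @param definedFields number of standard BED columns (3..12).
#' @param extraFields number of additional unnamed columns.
#' @return an [AutoSql-class].
#' @export
autoSqlForBed <- function(definedFields, extraFields = 0L) {
  stopifnot(definedFields >= 3L, definedFields <= 12L, extraFields >= 0L)
  f <- .bedStdFields[seq_len(definedFields), ]
  if (extraFields > 0L)
    f <- rbind(f, data.frame(
      type = rep("string", extraFields),
      name = paste0("field", definedFields + seq_len(extraFields)),
      comment = rep("Undocumented extra field", extraFields)))
  new("AutoSql",
      name = sprintf("bed%d", definedFields),
      comment = "Browser Extensible Data",
      fields = f)
}
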