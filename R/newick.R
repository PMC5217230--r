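#' Parse a Newick string into a labeled tree
#'
#' Reads a single rooted Newick tree. Unlike leaf-centric readers, internal
#' node labels are kept as sample names, and a label may encode several
#' co-located names joined by `label_delimiter` (the dialect used to
#' serialize collapsed trees; a plain Newick parser sees such a label as one
#' ordinary string, so the dialect round-trips through standard tools).
#' Square-bracket comments are stripped before parsing. Branch lengths absent
#' from the text default to 0; negative lengths are kept as written.
#'
#' @param text A single Newick string, terminated by `;`.
#' @param label_delimiter Delimiter splitting multi-name labels (default
#'   `"|"`).
#' @return A [labeled_tree()].
#' @examples
#' parse_newick("(S1:2,S2:3)S:0;")
#' parse_newick("((A:1,B:1):1,C:2);")
#' @export
parse_newick <- function(text, label_delimiter = "|") {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("\\[[^]]*\\]", "", text)
  src <- text
  nc <- nchar(src)
  pos <- 1L

  peek <- function() if (pos > nc) "" else substr(src, pos, pos)
  skip_ws <- function() {
    while (pos <= nc && substr(src, pos, pos) %in% c(" ", "\t", "\r", "\n"))
      pos <<- pos + 1L
  }
  fail <- function(msg) {
    stop(sprintf("newick parse error at offset %d: %s", pos, msg), call. = FALSE)
  }

  # accumulators for the flat node table
  parent <- integer(0); children <- list(); names_ <- list()
  blen <- numeric(0); day <- integer(0)
  new_node <- function() {
    idx <- length(parent) + 1L
    parent[idx] <<- 0L; children[[idx]] <<- integer(0)
    names_[[idx]] <<- character(0); blen[idx] <<- NA_real_
    day[idx] <<- NA_integer_
    idx
  }

  read_label <- function() {
    skip_ws()
    start <- pos
    while (pos <= nc && !(substr(src, pos, pos) %in% c("(", ")", ",", ":", ";")))
      pos <<- pos + 1L
    lab <- trimws(substr(src, start, pos - 1L))
    if (!nzchar(lab)) return(character(0))
    parts <- strsplit(lab, label_delimiter, fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    parts
  }

  read_blen <- function() {
    skip_ws()
    rest <- substr(src, pos, nc)
    m <- regexpr("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?", rest)
    if (m == -1L) fail("expected a branch length after ':'")
    len <- attr(m, "match.length")
    val <- as.numeric(substr(rest, 1L, len))
    pos <<- pos + len
    val
  }

  parse_clade <- function() {
    skip_ws()
    idx <- new_node()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        child <- parse_clade()
        parent[child] <<- idx
        children[[idx]] <<- c(children[[idx]], child)
        skip_ws()
        ch <- peek()
        if (ch == ",") { pos <<- pos + 1L; next }
        if (ch == ")") { pos <<- pos + 1L; break }
        fail("expected ',' or ')'")
      }
    }
    names_[[idx]] <<- read_label()
    skip_ws()
    if (peek() == ":") {
      pos <<- pos + 1L
      blen[idx] <<- read_blen()
    }
    idx
  }

  root <- parse_clade()
  skip_ws()
  if (peek() != ";") fail("expected ';' terminating the tree")
  pos <- pos + 1L
  skip_ws()
  if (pos <= nc) fail("trailing characters after ';'")

  blen[is.na(blen)] <- 0
  blen[root] <- NA_real_
  labeled_tree(parent, children, names_, blen, day)
}

#' Serialize a labeled tree to Newick
#'
#' Deterministic writer: children are emitted in stored order; multi-name
#' nodes emit their names joined by `label_delimiter`; every non-root branch
#' carries an explicit length printed with `digits` significant digits. The
#' root never carries a branch length, so a root-only tree named `S` is
#' written `"S;"`.
#'
#' @param tree A [labeled_tree()].
#' @param file Optional path; when given the string is written to it and
#'   returned invisibly.
#' @param label_delimiter Delimiter joining multi-name labels (default `"|"`).
#' @param digits Significant digits for branch lengths (default 6).
#' @return The Newick string.
#' @examples
#' write_newick(parse_newick("((A:1,B:1):1,C:2);"))
#' @export
write_newick <- function(tree, file = NULL, label_delimiter = "|", digits = 6) {
  bad <- grepl("[(),:;\\[\\]' \t\n]", unlist(tree$names, use.names = FALSE), perl = TRUE) |
    grepl(label_delimiter, unlist(tree$names, use.names = FALSE), fixed = TRUE)
  if (any(bad))
    stop("sample name(s) contain the delimiter or Newick metacharacters: ",
         paste(unlist(tree$names)[bad], collapse = ", "), call. = FALSE)
  fmt <- function(x) sprintf("%.*g", digits, x)
  rec <- function(i) {
    label <- paste(tree$names[[i]], collapse = label_delimiter)
    kids <- tree$children[[i]]
    body <- if (length(kids))
      paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")")
    else ""
    s <- paste0(body, label)
    if (i != tree$root) s <- paste0(s, ":", fmt(tree$blen[i]))
    s
  }
  out <- paste0(rec(tree$root), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Read / write Newick files
#'
#' One tree per file, trailing semicolon required, UTF-8; `[...]` comments
#' are ignored.
#'
#' @param file Path to a Newick file.
#' @param label_delimiter Multi-name label delimiter (see [parse_newick()]).
#' @return A [labeled_tree()].
#' @export
read_newick <- function(file, label_delimiter = "|") {
  parse_newick(paste(readLines(file, warn = FALSE), collapse = ""),
               label_delimiter = label_delimiter)
}
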