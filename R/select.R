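# Atom selection mini-language.
#
# Grammar (case-insensitive keywords, left-to-right, 'not' binds tightest):
#   expr     := and_expr ('or' and_expr)*
#   and_expr := not_expr ('and' not_expr)*
#   not_expr := 'not' not_expr | primary
#   primary  := '(' expr ')'
#             | 'all' | 'none' | 'heavy' | 'hydrogen' | 'backbone'
#             | 'chain' <id> | 'resid' <n>[:<m>] | 'resname' <name>
#             | 'name' <atom-name>
#             | 'within' <R> 'of' primary
#             | <group-name>            (looked up in `groups`)
#
# 'backbone' matches atom names N, CA, C, O. 'within R of X' selects whole
# residues whose minimum heavy-atom distance to the heavy atoms of X is
# <= R Angstrom, evaluated on the designated reference frame only, so pocket
# membership is frozen rather than per-frame.

.BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Select atoms of a topology by expression
#'
#' @param top a [topology()].
#' @param expression selection string (see Details in the package vignette).
#' @param ref reference coordinates (N x 3 matrix) required by `within`
#'   clauses; pocket membership is evaluated on this frame only.
#' @param groups named list of integer atom-index vectors that bare
#'   identifiers in the expression (e.g. `ligand`) resolve to.
#' @return sorted integer vector of 1-based atom indices.
#' @export
select_atoms <- function(top, expression, ref = NULL, groups = list()) {
  stopifnot(inherits(top, "topology"), is.character(expression), length(expression) == 1L)
  toks <- .sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- .sel_expr(st, top, ref, groups, expression)
  if (st$pos <= nrow(st$toks)) {
    .sel_err(expression, st$toks$at[st$pos],
             sprintf("unexpected token '%s'", st$toks$text[st$pos]))
  }
  which(mask)
}

.sel_tokenize <- function(expr) {
  pat <- "\\(|\\)|:|[A-Za-z0-9_.'*+-]+"
  m <- gregexpr(pat, expr)[[1]]
  if (m[1] == -1L) .sel_err(expr, 1L, "empty selection")
  text <- regmatches(expr, gregexpr(pat, expr))[[1]]
  data.frame(text = text, at = as.integer(m), stringsAsFactors = FALSE)
}

.sel_err <- function(expr, at, msg) {
  stop(sprintf("selection parse error at position %d in '%s': %s", at, expr, msg))
}

.sel_peek <- function(st) if (st$pos <= nrow(st$toks)) tolower(st$toks$text[st$pos]) else ""
.sel_take <- function(st) {
  t <- st$toks[st$pos, ]
  st$pos <- st$pos + 1L
  t
}

.sel_expr <- function(st, top, ref, groups, expr) {
  left <- .sel_and(st, top, ref, groups, expr)
  while (.sel_peek(st) == "or") {
    .sel_take(st)
    left <- left | .sel_and(st, top, ref, groups, expr)
  }
  left
}

.sel_and <- function(st, top, ref, groups, expr) {
  left <- .sel_not(st, top, ref, groups, expr)
  while (.sel_peek(st) == "and") {
    .sel_take(st)
    left <- left & .sel_not(st, top, ref, groups, expr)
  }
  left
}

.sel_not <- function(st, top, ref, groups, expr) {
  if (.sel_peek(st) == "not") {
    .sel_take(st)
    return(!.sel_not(st, top, ref, groups, expr))
  }
  .sel_primary(st, top, ref, groups, expr)
}

.sel_primary <- function(st, top, ref, groups, expr) {
  if (st$pos > nrow(st$toks)) {
    .sel_err(expr, nchar(expr) + 1L, "unexpected end of expression")
  }
  tok <- .sel_take(st)
  word <- tolower(tok$text)
  at <- top$atoms
  n <- nrow(at)
  switch(word,
    "(" = {
      out <- .sel_expr(st, top, ref, groups, expr)
      if (.sel_peek(st) != ")") .sel_err(expr, tok$at, "unbalanced parenthesis")
      .sel_take(st)
      out
    },
    "all" = rep(TRUE, n),
    "none" = rep(FALSE, n),
    "heavy" = at$element != "H",
    "hydrogen" = at$element == "H",
    "backbone" = at$name %in% .BACKBONE_NAMES,
    "chain" = {
      arg <- .sel_arg(st, expr, tok$at, "chain identifier")
      at$chain == arg$text
    },
    "resname" = {
      arg <- .sel_arg(st, expr, tok$at, "residue name")
      toupper(at$res_name) == toupper(arg$text)
    },
    "name" = {
      arg <- .sel_arg(st, expr, tok$at, "atom name")
      toupper(at$name) == toupper(arg$text)
    },
    "resid" = {
      a <- .sel_arg(st, expr, tok$at, "residue number")
      lo <- suppressWarnings(as.integer(a$text))
      if (is.na(lo)) .sel_err(expr, a$at, sprintf("'%s' is not a residue number", a$text))
      hi <- lo
      if (.sel_peek(st) == ":") {
        .sel_take(st)
        b <- .sel_arg(st, expr, tok$at, "residue number")
        hi <- suppressWarnings(as.integer(b$text))
        if (is.na(hi)) .sel_err(expr, b$at, sprintf("'%s' is not a residue number", b$text))
      }
      at$res_seq >= lo & at$res_seq <= hi
    },
    "within" = {
      a <- .sel_arg(st, expr, tok$at, "distance")
      r <- suppressWarnings(as.numeric(a$text))
      if (is.na(r) || r < 0) .sel_err(expr, a$at, sprintf("'%s' is not a distance", a$text))
      of <- .sel_take(st)
      if (tolower(of$text) != "of") .sel_err(expr, of$at, "'within <R>' must be followed by 'of'")
      target <- .sel_primary(st, top, ref, groups, expr)
      .sel_within(top, target, r, ref)
    },
    {
      if (!is.null(groups[[tok$text]])) {
        mask <- rep(FALSE, n)
        mask[groups[[tok$text]]] <- TRUE
        mask
      } else {
        .sel_err(expr, tok$at, sprintf("unknown keyword or group '%s'", tok$text))
      }
    }
  )
}

.sel_arg <- function(st, expr, at, what) {
  if (st$pos > nrow(st$toks)) .sel_err(expr, at, paste("missing", what))
  .sel_take(st)
}

# residue-level within-R: residues with any heavy atom at distance <= R
# (inclusive) of any heavy atom of the target selection
.sel_within <- function(top, target_mask, r, ref) {
  if (is.null(ref)) {
    stop("'within' selections need a reference frame (argument ref)")
  }
  at <- top$atoms
  stopifnot(is.matrix(ref), nrow(ref) == nrow(at))
  heavy <- at$element != "H"
  tgt <- which(target_mask & heavy)
  mask <- rep(FALSE, nrow(at))
  if (length(tgt) == 0L) return(mask)
  res_key <- paste(at$chain, at$res_seq)
  cand <- which(heavy)
  d2 <- .cross_dist2(ref[cand, , drop = FALSE], ref[tgt, , drop = FALSE])
  mind <- sqrt(apply(d2, 1L, min))
  hit_res <- unique(res_key[cand[mind <= r]])
  mask[res_key %in% hit_res] <- TRUE
  mask
}

# squared distances between rows of a (n x 3) and b (m x 3)
.cross_dist2 <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
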