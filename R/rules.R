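#' Metapath rules
#'
#' A rule (metapath) is a typed relation sequence predicting the target
#' relation between its endpoints: e.g. the body
#' `Compound -CuG-> Gene -GrG-> Gene -DaG^-1-> Disease` predicts `CtD`
#' between its Compound head and Disease tail wherever the body grounds.
#' Rules are fully general: bodies contain node types and relation labels,
#' never entity constants.
#'
#' `kg_rule()` builds a single rule; rule sets are data.frames of class
#' `kg_rules` with columns `confidence`, `support`, `body_groundings`,
#' `target`, `body`, `provenance`.
#'
#' @param target target relation label
#' @param relations character vector, the body's relation labels (length L)
#' @param types character vector of node types (length L + 1), head first
#' @return an object of class `kg_rule`
#' @export
kg_rule <- function(target, relations, types) {
  stopifnot(length(relations) >= 1L, length(types) == length(relations) + 1L)
  if (length(relations) == 1L && relations[[1L]] == target) {
    stop("degenerate rule: body equal to the target relation")
  }
  structure(list(target = target,
                 relations = as.character(relations),
                 types = as.character(types)),
            class = "kg_rule")
}

#' @export
print.kg_rule <- function(x, ...) {
  cat(x$target, "<=", kg_format_body(x), "\n")
  invisible(x)
}

#' @export
format.kg_rule <- function(x, ...) kg_format_body(x)

#' Serialize a rule body as `Type -rel-> Type -rel-> ...`
#' @param rule a `kg_rule`
#' @return a single string
#' @export
kg_format_body <- function(rule) {
  L <- length(rule$relations)
  out <- rule$types[1L]
  for (i in seq_len(L)) {
    out <- paste0(out, " -", rule$relations[i], "-> ", rule$types[i + 1L])
  }
  out
}

#' Parse a rule body string back into a `kg_rule`
#'
#' Inverse of [kg_format_body()]. Relation labels must not contain spaces;
#' node types may (e.g. `Side Effect`).
#' @param body body string
#' @param target target relation label
#' @return a `kg_rule`
#' @export
kg_parse_body <- function(body, target) {
  seps <- gregexpr(" -[^ ]+-> ", body)[[1L]]
  if (seps[1L] == -1L) stop("unparseable rule body: ", body)
  lens <- attr(seps, "match.length")
  rels <- substring(body, seps + 2L, seps + lens - 4L)
  starts <- c(1L, seps + lens)
  ends <- c(seps - 1L, nchar(body))
  types <- substring(body, starts, ends)
  kg_rule(target, rels, types)
}

rule_key <- function(rule) paste0(rule$target, "\r", kg_format_body(rule))

# Build a kg_rules data.frame from a list of kg_rule objects + stats.
new_rules_df <- function(rules, support = NA_integer_,
                         body_groundings = NA_integer_,
                         confidence = NA_real_, provenance = "mined") {
  df <- data.frame(
    confidence = rep_len(confidence, length(rules)),
    support = rep_len(support, length(rules)),
    body_groundings = rep_len(body_groundings, length(rules)),
    target = vapply(rules, function(r) r$target, ""),
    body = vapply(rules, kg_format_body, ""),
    provenance = rep_len(provenance, length(rules)),
    stringsAsFactors = FALSE)
  class(df) <- c("kg_rules", "data.frame")
  df
}

#' Parse every body in a rule set
#' @param rules a `kg_rules` data.frame
#' @return list of `kg_rule` objects
#' @export
kg_rules_parsed <- function(rules) {
  Map(kg_parse_body, rules$body, rules$target, USE.NAMES = FALSE)
}

#' Read / write rule sets as TSV
#'
#' Format: header `confidence	support	body_groundings	target	body`,
#' one rule per line. This file doubles as the prior-rule input of the
#' trainable generator. Extra numeric columns (e.g. `rule_quality_H`,
#' `omega`) survive a round trip.
#' @param rules a `kg_rules` data.frame
#' @param path file path
#' @return `kg_rules_read`: a `kg_rules` data.frame; `kg_rules_write`:
#'   `path` invisibly
#' @export
kg_rules_write <- function(rules, path) {
  utils::write.table(rules, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname kg_rules_write
#' @export
kg_rules_read <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = NA, quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("confidence", "support", "body_groundings", "target", "body")
  if (!all(need %in% names(df))) {
    stop("rule file lacks columns: ", paste(setdiff(need, names(df)),
                                            collapse = ", "))
  }
  class(df) <- c("kg_rules", "data.frame")
  df
}

#' @export
print.kg_rules <- function(x, n = 10L, ...) {
  cat(sprintf("Rule set: %d rule(s) for target(s) %s\n", nrow(x),
              paste(unique(x$target), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat("...", nrow(x) - n, "more rule(s)\n")
  invisible(x)
}

# Type a bare relation sequence using the graph's relation signatures.
# Returns NULL when a relation is unknown; rules whose type chain does not
# join are still constructed (they simply never ground).
rule_from_relations <- function(target, relations, signature) {
  sig_h <- structure(signature$head_type, names = signature$relation)
  sig_t <- structure(signature$tail_type, names = signature$relation)
  ht <- tt <- character(length(relations))
  for (i in seq_along(relations)) {
    r <- relations[i]
    if (is_inverse_label(r)) {
      b <- kg_inverse_label(r)
      if (!b %in% names(sig_h)) return(NULL)
      ht[i] <- sig_t[[b]]; tt[i] <- sig_h[[b]]
    } else {
      if (!r %in% names(sig_h)) return(NULL)
      ht[i] <- sig_h[[r]]; tt[i] <- sig_t[[r]]
    }
  }
  if (length(relations) == 1L && relations[[1L]] == target) return(NULL)
  kg_rule(target, relations, c(ht[1L], tt))
}
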