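#' Construct a gene set
#'
#' @param name set name.
#' @param members unique gene identifiers.
#' @param description free text (GMT second field).
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, members, description = "") {
  members <- as.character(members)
  if (anyDuplicated(members)) members <- unique(members)
  structure(list(name = as.character(name),
                 description = as.character(description),
                 members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$members), " genes\n", sep = "")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then members, tab-delimited. Members
#' duplicated within a line are dropped with a warning.
#'
#' @param path GMT file path.
#' @return named list of [gene_set()] objects.
#' @export
read_gene_set_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("'", path, "' contains no gene sets", call. = FALSE)
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has ", length(f),
           " field(s); need name, description and at least one member",
           call. = FALSE)
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("GMT set '", f[1L], "' (line ", i,
              ") has duplicated members; deduplicated", call. = FALSE)
      members <- unique(members)
    }
    gene_set(f[1L], members, f[2L])
  })
  names(sets) <- vapply(sets, `[[`, character(1L), "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' Round-trips losslessly with [read_gene_set_gmt()].
#'
#' @param sets a `gene_set` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_set_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a signed gene signature
#'
#' A signature is an ordered list of up-regulated and down-regulated genes
#' with sign weights k = +1 on induced and k = -1 on suppressed genes — the
#' weights of the signed z-sum pathway score.
#'
#' @param up ordered identifiers of induced genes (k = +1).
#' @param down ordered identifiers of suppressed genes (k = -1).
#' @return an object of class `gene_signature`.
#' @export
gene_signature <- function(up, down) {
  up <- as.character(up); down <- as.character(down)
  if (anyDuplicated(up) || anyDuplicated(down))
    stop("duplicate gene within up or down list", call. = FALSE)
  overlap <- intersect(up, down)
  if (length(overlap))
    stop("gene(s) in both up and down lists: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  structure(list(up = up, down = down), class = "gene_signature")
}

#' Sign weights of a signature
#' @param sig a [gene_signature()].
#' @return named numeric vector of +1/-1, up genes first.
#' @export
signature_k <- function(sig) {
  stats::setNames(c(rep(1, length(sig$up)), rep(-1, length(sig$down))),
                  c(sig$up, sig$down))
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature> ", length(x$up), " up (k=+1), ",
      length(x$down), " down (k=-1)\n", sep = "")
  invisible(x)
}

#' Serialize a signature as a two-set GMT
#'
#' @param sig a [gene_signature()].
#' @param path output path.
#' @param up_name,down_name set names used in the file.
#' @return `path`, invisibly.
#' @export
write_signature_gmt <- function(sig, path, up_name = "SIG_UP",
                                down_name = "SIG_DOWN") {
  write_gene_set_gmt(list(
    gene_set(up_name, sig$up, "induced genes, k=+1"),
    gene_set(down_name, sig$down, "suppressed genes, k=-1")), path)
}

#' Read a signature from a two-set GMT
#'
#' @param path GMT path holding the up set and the down set (in that order,
#'   or named via `up_name`/`down_name`).
#' @param up_name,down_name set names expected in the file.
#' @return a [gene_signature()].
#' @export
read_signature_gmt <- function(path, up_name = "SIG_UP",
                               down_name = "SIG_DOWN") {
  sets <- read_gene_set_gmt(path)
  if (all(c(up_name, down_name) %in% names(sets)))
    return(gene_signature(sets[[up_name]]$members, sets[[down_name]]$members))
  if (length(sets) != 2L)
    stop("signature GMT must hold exactly the up and down sets", call. = FALSE)
  gene_signature(sets[[1L]]$members, sets[[2L]]$members)
}
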