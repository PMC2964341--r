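#' Three-set Venn region counts of per-readout hit lists
#'
#' Counts the seven regions of a three-set Venn diagram over a shared
#' target namespace; region counts sum to the size of the union.
#'
#' @param hit_lists named list of exactly three character vectors of hit
#'   target ids
#' @return named integer vector: `A_only`, `B_only`, `C_only`, `AB`, `AC`,
#'   `BC`, `ABC` (A, B, C in list order), with the set names as an
#'   attribute
#' @export
#' @examples
#' venn_overlap(list(rps2 = c("x", "y"), enp1 = c("y", "z"), rpl29 = "y"))
venn_overlap <- function(hit_lists) {
  stopifnot(is.list(hit_lists), length(hit_lists) == 3)
  A <- unique(hit_lists[[1]]); B <- unique(hit_lists[[2]])
  C <- unique(hit_lists[[3]])
  u <- union(union(A, B), C)
  inA <- u %in% A; inB <- u %in% B; inC <- u %in% C
  out <- c(
    A_only = sum(inA & !inB & !inC),
    B_only = sum(!inA & inB & !inC),
    C_only = sum(!inA & !inB & inC),
    AB = sum(inA & inB & !inC),
    AC = sum(inA & !inB & inC),
    BC = sum(!inA & inB & inC),
    ABC = sum(inA & inB & inC)
  )
  attr(out, "sets") <- names(hit_lists)
  out
}

#' Per-category hit distribution
#'
#' For each functional category of the target catalog (ribosomal proteins,
#' NPC components, nuclear transport, ribosome synthesis, miscellaneous):
#' how many targets were screened, how many were hits, and the hit
#' fraction. Every hit must be catalogued.
#'
#' @param hits character vector of hit target ids
#' @param catalog data.frame with `target` and `category`
#' @param screened character vector of all screened target ids (default:
#'   every catalog target)
#' @return data.frame: category, n_screened, n_hits, hit_fraction
#' @export
category_report <- function(hits, catalog, screened = catalog$target) {
  stopifnot(all(c("target", "category") %in% names(catalog)))
  if (anyDuplicated(catalog$target)) stop("catalog has duplicated targets")
  uncat <- setdiff(hits, catalog$target)
  if (length(uncat)) stop("hit(s) missing from the catalog: ",
                          paste(uncat, collapse = ", "))
  cat_of <- stats::setNames(catalog$category, catalog$target)
  cats <- unique(catalog$category)
  out <- do.call(rbind, lapply(cats, function(cc) {
    scr <- sum(cat_of[screened] == cc, na.rm = TRUE)
    nh <- sum(cat_of[hits] == cc, na.rm = TRUE)
    data.frame(category = cc, n_screened = scr, n_hits = nh,
               hit_fraction = if (scr > 0) nh / scr else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
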