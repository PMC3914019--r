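#' Simulate a multi-generation pedigree with admixed founders
#'
#' Builds a family cohort of the kind seen in community family studies:
#' a founder generation drawn from two ancestral populations, followed by
#' `n_generations` generations of offspring. Mating pairs are formed at
#' random within the previous generation, avoiding parent-child, full-sib
#' and half-sib unions; with probability `p_remate` an individual takes a
#' second mate, which creates half-sib and avuncular structures. When a
#' generation admits no valid new pairing (e.g. all its members are
#' siblings), existing couples from earlier generations reproduce again,
#' so small pedigrees stay connected without introducing extra founders.
#'
#' @param n_founders number of founders (>= 2).
#' @param n_generations number of offspring generations (>= 1).
#' @param mean_offspring mean number of children per couple (Poisson).
#' @param admixture_fraction fraction of founders from population B.
#' @param p_remate probability that a paired individual takes a second mate.
#' @param seed integer seed; fixed seed fixes the pedigree exactly.
#' @return a `pedigree_table`: a data.frame with columns `individual_id`,
#'   `father_id`, `mother_id` (NA for founders), `sex` (1 = male, 2 =
#'   female), `generation`, and `founder_population` ("A"/"B" for
#'   founders, NA otherwise). Parents always precede children.
#' @export
generate_pedigree <- function(n_founders, n_generations, mean_offspring = 2.5,
                              admixture_fraction = 0, p_remate = 0.2,
                              seed = 1L) {
  n_founders <- check_count(n_founders, "n_founders", min = 2L)
  n_generations <- check_count(n_generations, "n_generations", min = 1L)
  if (mean_offspring <= 0) stop_invalid("`mean_offspring` must be positive")
  check_prob(admixture_fraction, "admixture_fraction")
  check_prob(p_remate, "p_remate")

  set.seed(seed)
  n_b <- round(n_founders * admixture_fraction)
  pop <- sample(rep(c("A", "B"), c(n_founders - n_b, n_b)))
  ped <- data.frame(
    individual_id = sprintf("F%03d", seq_len(n_founders)),
    father_id = NA_character_, mother_id = NA_character_,
    sex = rep_len(c(1L, 2L), n_founders),
    generation = 0L,
    founder_population = pop,
    stringsAsFactors = FALSE
  )

  next_id <- 1L
  for (g in seq_len(n_generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    couples <- .form_couples(prev, ped, p_remate)
    if (nrow(couples) == 0L) {
      # no valid pairing in this generation: re-use established couples
      kids <- ped[!is.na(ped$father_id), ]
      if (nrow(kids) == 0L) {
        couples <- data.frame(father = ped$individual_id[ped$sex == 1L][1L],
                              mother = ped$individual_id[ped$sex == 2L][1L],
                              stringsAsFactors = FALSE)
      } else {
        couples <- unique(kids[, c("father_id", "mother_id")])
        names(couples) <- c("father", "mother")
      }
    }
    children <- NULL
    repeat {
      n_kids <- rpois(nrow(couples), mean_offspring)
      if (sum(n_kids) > 0L) break
    }
    for (k in seq_len(nrow(couples))) {
      if (n_kids[k] == 0L) next
      ids <- sprintf("G%d_%03d", g, next_id:(next_id + n_kids[k] - 1L))
      next_id <- next_id + n_kids[k]
      children <- rbind(children, data.frame(
        individual_id = ids,
        father_id = couples$father[k], mother_id = couples$mother[k],
        sex = sample(c(1L, 2L), n_kids[k], replace = TRUE),
        generation = g, founder_population = NA_character_,
        stringsAsFactors = FALSE
      ))
    }
    ped <- rbind(ped, children)
  }
  class(ped) <- c("pedigree_table", "data.frame")
  validate_pedigree(ped)
  ped
}

## pair males and females of `prev`, avoiding unions that share a parent;
## remating duplicates some individuals into extra couples
.form_couples <- function(prev, ped, p_remate) {
  males <- prev$individual_id[prev$sex == 1L]
  females <- prev$individual_id[prev$sex == 2L]
  if (length(males) == 0L || length(females) == 0L)
    return(data.frame(father = character(), mother = character(),
                      stringsAsFactors = FALSE))
  males <- sample(males, length(males))
  females <- sample(females, length(females))
  parent_of <- function(id) {
    i <- match(id, ped$individual_id)
    c(ped$father_id[i], ped$mother_id[i])
  }
  related <- function(m, f) {
    pm <- parent_of(m); pf <- parent_of(f)
    any(!is.na(pm) & !is.na(pf) & pm %in% pf)
  }
  couples <- NULL
  used_f <- logical(length(females))
  for (m in males) {
    ok <- which(!used_f & !vapply(females, related, logical(1), m = m))
    if (length(ok) == 0L) next
    j <- ok[1L]
    used_f[j] <- TRUE
    couples <- rbind(couples, data.frame(father = m, mother = females[j],
                                         stringsAsFactors = FALSE))
    # second mate with probability p_remate -> half-sib structures
    if (runif(1) < p_remate) {
      ok2 <- which(!used_f & !vapply(females, related, logical(1), m = m))
      if (length(ok2) > 0L) {
        j2 <- ok2[1L]
        used_f[j2] <- TRUE
        couples <- rbind(couples, data.frame(father = m, mother = females[j2],
                                             stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(couples))
    couples <- data.frame(father = character(), mother = character(),
                          stringsAsFactors = FALSE)
  couples
}

#' Validate the structural invariants of a pedigree table
#'
#' Checks that parents precede their children in storage order, that both
#' parents are present or both absent, that all parent links resolve, and
#' that no individual is its own ancestor.
#'
#' @param ped a `pedigree_table`.
#' @return `ped`, invisibly; errors if an invariant is violated.
#' @export
validate_pedigree <- function(ped) {
  req <- c("individual_id", "father_id", "mother_id")
  if (!all(req %in% names(ped))) stop_invalid("missing pedigree columns")
  if (anyDuplicated(ped$individual_id)) stop_invalid("duplicate individual ids")
  half <- xor(is.na(ped$father_id), is.na(ped$mother_id))
  if (any(half)) stop_invalid("individuals with exactly one parent recorded")
  idx <- seq_len(nrow(ped))
  fi <- match(ped$father_id, ped$individual_id)
  mi <- match(ped$mother_id, ped$individual_id)
  nonf <- !is.na(ped$father_id)
  if (any(nonf & (is.na(fi) | is.na(mi))))
    stop_invalid("parent id not present in pedigree")
  if (any(nonf & (fi >= idx | mi >= idx)))
    stop_invalid("parents must precede children in storage order (cycle?)")
  invisible(ped)
}

#' @export
print.pedigree_table <- function(x, ...) {
  nf <- sum(is.na(x$father_id))
  ngen <- if (!is.null(x$generation)) max(x$generation) + 1L else NA_integer_
  cat(sprintf("pedigree_table: %d individuals (%d founders, %s generations)\n",
              nrow(x), nf, ngen))
  if (nf > 0L) {
    tab <- table(x$founder_population[is.na(x$father_id)])
    cat("  founder populations:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a pedigree in PLINK .fam dialect
#'
#' Columns: FID IID PAT MAT SEX PHENO, with `0` for a missing parent. The
#' founder population label is carried in the FID column so that the file
#' round-trips.
#'
#' @param ped a `pedigree_table`.
#' @param path file path.
#' @return `write_fam` returns `path` invisibly; `read_fam` returns a
#'   `pedigree_table`.
#' @export
write_fam <- function(ped, path) {
  fid <- ifelse(is.na(ped$founder_population), "FAM", ped$founder_population)
  out <- data.frame(
    FID = fid, IID = ped$individual_id,
    PAT = ifelse(is.na(ped$father_id), "0", ped$father_id),
    MAT = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    SEX = ped$sex, PHENO = -9
  )
  write.table(out, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fam
#' @export
read_fam <- function(path) {
  x <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("FID", "IID", "PAT", "MAT", "SEX", "PHENO"))
  founder <- x$PAT == "0" & x$MAT == "0"
  ped <- data.frame(
    individual_id = x$IID,
    father_id = ifelse(x$PAT == "0", NA_character_, x$PAT),
    mother_id = ifelse(x$MAT == "0", NA_character_, x$MAT),
    sex = x$SEX,
    generation = NA_integer_,
    founder_population = ifelse(founder & x$FID %in% c("A", "B"), x$FID,
                                ifelse(founder, "A", NA_character_)),
    stringsAsFactors = FALSE
  )
  # reconstruct generation from parent links
  gen <- integer(nrow(ped))
  for (i in seq_len(nrow(ped))) {
    if (is.na(ped$father_id[i])) next
    gen[i] <- 1L + max(gen[match(c(ped$father_id[i], ped$mother_id[i]),
                                 ped$individual_id)])
  }
  ped$generation <- gen
  class(ped) <- c("pedigree_table", "data.frame")
  validate_pedigree(ped)
  ped
}
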