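# Defense-system assembly. A defense family's genetic-organization rule has
# three thresholds: MG (minimum number of mandatory genes), SG (minimum
# total genes) and d_max (maximum number of intervening genes between
# consecutive member genes). Hits of one family on one contig are chained
# greedily left-to-right while gaps stay <= d_max; each chain is a system,
# complete when it satisfies both MG and SG.

#' Build a rule set from a data.frame
#'
#' @param df data.frame with columns `family`, `gene_name`, `role`
#'   (mandatory/accessory), `mg`, `sg`, `d_max`; one row per gene profile,
#'   thresholds constant within a family.
#' @return a `defense_rules` list keyed by family with elements
#'   `mandatory`, `accessory`, `mg`, `sg`, `d_max`.
#' @export
defense_rules <- function(df) {
  need <- c("family", "gene_name", "role", "mg", "sg", "d_max")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("rules table lacks column(s): ", paste(miss, collapse = ","))
  rules <- lapply(split(df, df$family), function(d) {
    role <- tolower(d$role)
    list(mandatory = unique(d$gene_name[role == "mandatory"]),
         accessory = unique(d$gene_name[role == "accessory"]),
         mg = as.integer(d$mg[1]), sg = as.integer(d$sg[1]),
         d_max = as.integer(d$d_max[1]))
  })
  if (any(vapply(rules, function(r) r$d_max < 0, logical(1))))
    stop("d_max must be >= 0")
  structure(rules, class = "defense_rules")
}

#' Read a rules file (TSV)
#' @param path TSV with columns family, gene_name, role, mg, sg, d_max.
#' @return a [defense_rules()] object.
#' @export
read_defense_rules <- function(path) {
  raw <- .read_tsv(path)
  raw$mg <- as.integer(raw$mg)
  raw$sg <- as.integer(raw$sg)
  raw$d_max <- as.integer(raw$d_max)
  defense_rules(raw)
}

# Rule for a family absent from the rule set: a single-gene system family.
.default_rule <- function() list(mandatory = character(0),
                                 accessory = character(0),
                                 mg = 0L, sg = 1L, d_max = 0L)

#' Assemble defense systems from gene hits
#'
#' Joins defense annotations to gene coordinates and chains hits of the
#' same family along each contig (gap between consecutive members measured
#' in intervening genes, i.e. genes strictly between them). Chains meeting
#' the family's MG and SG thresholds are complete systems. Per-gene status
#' is `complete` (member of a complete system), `incomplete` (member of a
#' chain of >= 2 genes failing the thresholds) or `solitary` (single-gene
#' chain that is not a complete system).
#'
#' When the annotations already carry `system_id` assignments (e.g. from
#' DefenseFinder) assembly is skipped: provided systems are taken as
#' complete and unassigned genes as solitary.
#'
#' @param genes gene data.frame with ordinals (see [assign_ordinals()]).
#' @param hits defense annotation data.frame.
#' @param rules a [defense_rules()] object; families without a rule are
#'   treated as single-gene system families.
#' @return list with `systems` (data.frame: system_id, family, mag_id,
#'   contig_id, n_genes, n_mandatory, completeness, member_gene_ids) and
#'   `gene_status` (data.frame: gene_id, family, system_id, status).
#' @export
assemble_systems <- function(genes, hits, rules = NULL) {
  j <- match(hits$gene_id, genes$gene_id)
  if (anyNA(j)) {
    warning(sum(is.na(j)), " defense hit(s) without gene coordinates dropped")
    hits <- hits[!is.na(j), , drop = FALSE]
    j <- j[!is.na(j)]
  }
  h <- cbind(hits,
             genes[j, c("mag_id", "contig_id", "ordinal"), drop = FALSE])
  rownames(h) <- NULL

  if ("system_id" %in% names(h) && any(!is.na(h$system_id))) {
    assigned <- !is.na(h$system_id)
    sys <- do.call(rbind, lapply(split(h[assigned, ], h$system_id[assigned]),
      function(d) {
        d <- d[order(d$ordinal), , drop = FALSE]
        data.frame(system_id = d$system_id[1], family = d$family[1],
                   mag_id = d$mag_id[1], contig_id = d$contig_id[1],
                   n_genes = nrow(d),
                   n_mandatory = sum(d$role == "mandatory"),
                   completeness = "complete",
                   member_gene_ids = paste(d$gene_id, collapse = ","),
                   stringsAsFactors = FALSE)
      }))
    status <- data.frame(
      gene_id = h$gene_id, family = h$family, system_id = h$system_id,
      status = ifelse(assigned, "complete", "solitary"),
      stringsAsFactors = FALSE)
    return(list(systems = sys, gene_status = status))
  }

  unknown_profiles <- 0L
  sys_rows <- list()
  status_rows <- list()
  for (key in unique(paste(h$mag_id, h$contig_id, h$family, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    d <- h[h$mag_id == parts[1] & h$contig_id == parts[2] &
             h$family == parts[3], , drop = FALSE]
    d <- d[order(d$ordinal), , drop = FALSE]
    rule <- if (!is.null(rules) && parts[3] %in% names(rules))
      rules[[parts[3]]] else .default_rule()
    known <- c(rule$mandatory, rule$accessory)
    if (length(known) > 0) {
      extra <- !(d$gene_name %in% known)
      unknown_profiles <- unknown_profiles + sum(extra)
      mand <- d$gene_name %in% rule$mandatory
    } else {
      mand <- d$role == "mandatory"
    }
    gap <- diff(d$ordinal) - 1L
    chain <- cumsum(c(0L, as.integer(gap > rule$d_max)))
    for (cid in unique(chain)) {
      sel <- chain == cid
      n <- sum(sel)
      n_mand <- sum(mand[sel])
      complete <- n_mand >= rule$mg && n >= rule$sg
      sid <- sprintf("%s|%s|%s|%d", parts[1], parts[2], parts[3], cid + 1L)
      sys_rows[[length(sys_rows) + 1L]] <- data.frame(
        system_id = sid, family = parts[3], mag_id = parts[1],
        contig_id = parts[2], n_genes = n, n_mandatory = n_mand,
        completeness = if (complete) "complete" else "incomplete",
        member_gene_ids = paste(d$gene_id[sel], collapse = ","),
        stringsAsFactors = FALSE)
      st <- if (complete) "complete" else if (n >= 2) "incomplete"
            else "solitary"
      status_rows[[length(status_rows) + 1L]] <- data.frame(
        gene_id = d$gene_id[sel], family = parts[3], system_id = sid,
        status = st, stringsAsFactors = FALSE)
    }
  }
  if (unknown_profiles > 0)
    warning(unknown_profiles,
            " hit(s) with gene_name absent from the family rule ",
            "counted as accessory")
  systems <- if (length(sys_rows) > 0) do.call(rbind, sys_rows) else
    data.frame(system_id = character(0), family = character(0),
               mag_id = character(0), contig_id = character(0),
               n_genes = integer(0), n_mandatory = integer(0),
               completeness = character(0), member_gene_ids = character(0))
  gene_status <- if (length(status_rows) > 0) do.call(rbind, status_rows)
    else data.frame(gene_id = character(0), family = character(0),
                    system_id = character(0), status = character(0))
  rownames(systems) <- rownames(gene_status) <- NULL
  list(systems = systems, gene_status = gene_status)
}

#' Per-family defensome inventory
#'
#' @param assembly result of [assemble_systems()].
#' @param genes optional gene table; when given, `mag_id` is attached so the
#'   inventory can be split by MAG.
#' @return data.frame with one row per (mag, family): number of systems,
#'   complete systems, defense genes, and solitary genes. Genes in complete
#'   systems + genes in incomplete systems + solitary genes = total defense
#'   genes.
#' @export
defense_gene_inventory <- function(assembly, genes = NULL) {
  st <- assembly$gene_status
  sys <- assembly$systems
  if (!is.null(genes)) {
    st$mag_id <- genes$mag_id[match(st$gene_id, genes$gene_id)]
  } else {
    st$mag_id <- sys$mag_id[match(st$system_id, sys$system_id)]
  }
  if (nrow(st) == 0)
    return(data.frame(mag_id = character(0), family = character(0),
                      n_systems = integer(0), n_complete = integer(0),
                      n_genes = integer(0), n_solitary = integer(0)))
  out <- do.call(rbind, lapply(
    split(st, list(st$mag_id, st$family), drop = TRUE), function(d) {
      sids <- unique(d$system_id[!is.na(d$system_id)])
      ssub <- sys[sys$system_id %in% sids, , drop = FALSE]
      data.frame(mag_id = d$mag_id[1], family = d$family[1],
                 n_systems = nrow(ssub),
                 n_complete = sum(ssub$completeness == "complete"),
                 n_genes = nrow(d),
                 n_solitary = sum(d$status == "solitary"),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out[order(out$mag_id, out$family), , drop = FALSE]
}
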