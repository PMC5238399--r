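#' The 169 crucial drought-responsive genes
#'
#' The published second-round selection: 169 gene identifiers with their
#' Venn masks and categories (37 RDR, 35 SDR, 97 CDR across seven
#' subgroups), packaged as a reference fixture for the classification and
#' network stages.
#'
#' @return A tibble of class `category_assignment` with columns `gene_id`,
#'   `mask`, `category`.
#' @examples
#' dplyr::count(table3_fixture(), mask)
#' @export
table3_fixture <- function() {
  rows <- list(
  list(mask = "RT-R", genes = c(
    "BnaC03g56210D", "BnaCnng59500D", "BnaA05g01040D", "BnaCnng20790D",
    "BnaC09g44020D", "BnaC03g12620D", "BnaC01g37110D", "BnaA02g18900D",
    "BnaC07g19090D", "BnaA05g28740D", "BnaC05g09790D", "BnaA10g07930D",
    "BnaC01g34960D", "BnaA06g03410D", "BnaA03g24880D", "BnaA03g03260D",
    "BnaA02g11330D", "BnaA03g34560D", "BnaC03g58100D", "BnaC09g15390D",
    "BnaC04g18800D"
  )),
  list(mask = "RT-R+S-R", genes = c(
    "BnaA03g58830D", "BnaC04g08480D", "BnaAnng21300D", "BnaA08g28220D",
    "BnaC01g17200D", "BnaA03g06740D", "BnaA08g14940D", "BnaC01g15100D",
    "BnaA07g06750D", "BnaA10g13870D", "BnaC04g25850D", "BnaAnng32880D",
    "BnaA06g30800D", "BnaC02g09490D", "BnaC04g24050D", "BnaA03g51150D"
  )),
  list(mask = "ST-S", genes = c(
    "BnaA09g29930D", "BnaA01g15420D", "BnaA10g19500D"
  )),
  list(mask = "S-R+ST-S", genes = c(
    "BnaC04g53040D", "BnaA07g25920D", "BnaC03g21190D", "BnaA06g16790D",
    "BnaAnng38110D", "BnaC07g23420D", "BnaA05g07610D", "BnaC09g30400D",
    "BnaA05g04050D", "BnaC01g15930D", "BnaA10g25810D", "BnaA08g10720D",
    "BnaC08g34950D", "BnaAnng13920D", "BnaA05g01210D", "BnaC06g27540D",
    "BnaA09g45070D", "BnaA02g35770D", "BnaCnng49200D", "BnaAnng16550D",
    "BnaC01g01680D", "BnaC01g00790D", "BnaC04g12030D", "BnaC07g22910D",
    "BnaC09g13640D", "BnaC04g40560D", "BnaAnng35070D", "BnaC06g40190D",
    "BnaA06g03560D", "BnaA08g15660D", "BnaCnng58050D", "BnaA08g15380D"
  )),
  list(mask = "S-R", genes = c(
    "BnaC04g08380D", "BnaC08g34220D", "BnaC09g25150D", "BnaC04g06610D",
    "BnaA05g36130D", "BnaA07g09990D", "BnaC06g40170D", "BnaC03g54190D",
    "BnaA04g19170D", "BnaC06g42330D", "BnaC01g32000D", "BnaA03g18320D",
    "BnaA03g17650D", "BnaA06g25710D", "BnaCnng24430D", "BnaC03g65980D",
    "BnaA10g01810D", "BnaA10g23290D", "BnaC02g29620D", "BnaC04g04810D",
    "BnaA05g25890D", "BnaA02g15580D", "BnaC06g19400D", "BnaA09g13870D",
    "BnaA09g13340D", "BnaA01g27050D", "BnaC03g71340D", "BnaA06g20540D",
    "BnaC04g47740D", "BnaA09g00640D", "BnaA07g30770D", "BnaC02g05370D",
    "BnaC07g47180D", "BnaC06g27550D", "BnaAnng19400D", "BnaA03g23600D",
    "BnaA02g05950D", "BnaC08g38290D", "BnaCnng16640D", "BnaC01g41100D",
    "BnaC02g43320D", "BnaA01g11120D", "BnaC09g40740D", "BnaC04g07040D",
    "BnaC04g47180D", "BnaC05g39240D", "BnaC08g07260D", "BnaC04g51180D",
    "BnaC03g10010D", "BnaA06g17920D", "BnaC03g43240D", "BnaC03g28890D",
    "BnaCnng65600D", "BnaC09g42520D", "BnaC04g19980D", "BnaAnng28200D",
    "BnaC01g25210D", "BnaC09g54060D", "BnaA02g30890D", "BnaC04g30340D",
    "BnaA04g09660D", "BnaC06g20800D", "BnaC03g15560D", "BnaA05g04030D",
    "BnaA07g09660D", "BnaA04g11170D", "BnaA02g32580D", "BnaC04g48100D",
    "BnaC03g30200D", "BnaAnng33710D", "BnaC05g20880D", "BnaC09g30440D"
  )),
  list(mask = "RT-R+ST-S", genes = c(
    "BnaA05g24610D", "BnaA03g36420D", "BnaA04g15830D", "BnaAnng27690D",
    "BnaA05g09600D", "BnaA03g55400D", "BnaC05g04100D", "BnaA02g16190D",
    "BnaA08g31100D", "BnaC09g21910D", "BnaA03g46430D", "BnaC09g28340D",
    "BnaC03g42310D", "BnaA09g55800D"
  )),
  list(mask = "RT-R+S-R+ST-S", genes = c(
    "BnaA04g17930D", "BnaA04g27940D", "BnaA05g27700D", "BnaA08g04230D",
    "BnaA09g41620D", "BnaA10g11530D", "BnaC01g39170D", "BnaC02g00830D",
    "BnaC03g02620D", "BnaC04g22390D", "BnaC09g48690D"
  )),
  NULL)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- purrr::map_dfr(rows, function(r) {
    tibble(gene_id = r$genes, mask = r$mask)
  })
  assign_categories(out)
}
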