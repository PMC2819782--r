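# Packaged fixtures

## london_pct_chd.csv

Published comparison of officially recorded CHD prevalence with income for
the 31 London Primary Care Trusts (PCTs): observed treated-prevalence
totals, expected totals from an external age-sex rate schedule (Health
Survey for England 2003 standard), the published relative risks and rank
columns, and average weekly household income (hundreds of pounds).

The table is reproduced verbatim from its source, including two known
quirks, which are deliberately **not** corrected here:

- The Islington row repeats Hillingdon's numbers exactly (observed 13,929,
  expected 14,408, income 7.2); this is an apparent transcription slip in
  the source and means the ranks 13 and 19 each appear twice.
- Two published relative risks differ from their own observed/expected
  quotient by one unit in the third decimal: City and Hackney
  (9030/8746 = 1.0325, published 1.033) and Croydon (17519/18868 = 0.9285,
  published 0.928).

Columns: `pct`, `observed`, `expected`, `rr_published`,
`rr_rank_published`, `income`, `income_rank_published`.
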