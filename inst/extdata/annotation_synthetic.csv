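drug_name,appetite_listed,taste_listed
app_listed01,TRUE,
app_listed02,TRUE,
app_listed03,TRUE,
app_listed04,TRUE,
app_listed05,TRUE,
app_listed06,TRUE,
app_listed07,TRUE,
app_listed08,TRUE,
app_listed09,TRUE,
app_listed10,TRUE,
app_listed11,TRUE,
app_listed12,TRUE,
app_listed13,TRUE,
app_listed14,TRUE,
app_listed15,TRUE,
app_listed16,TRUE,
app_listed17,TRUE,
app_listed18,TRUE,
app_listed19,TRUE,
app_unlisted01,FALSE,
app_unlisted02,FALSE,
app_unlisted03,FALSE,
app_unlisted04,FALSE,
app_unlisted05,FALSE,
taste_listed01,,TRUE
taste_listed02,,TRUE
taste_listed03,,TRUE
taste_listed04,,TRUE
taste_listed05,,TRUE
taste_unlisted01,,FALSE
taste_unlisted02,,FALSE
taste_unlisted03,,FALSE
taste_unlisted04,,FALSE
taste_unlisted05,,FALSE
taste_unlisted06,,FALSE
taste_unlisted07,,FALSE
taste_unlisted08,,FALSE
taste_unlisted09,,FALSE
taste_unlisted10,,FALSE
taste_unlisted11,,FALSE
taste_unlisted12,,FALSE
taste_unlisted13,,FALSE
taste_unlisted14,,FALSE
taste_unlisted15,,FALSE
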