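# Bundled name/address frequency pools for the synthetic cohort generator.
# Weighted toward common Anglo-Australian names, with spelling variants
# (Smith/Smyth, Ann/Anne, Clark/Clarke) so phonetic collisions occur at
# realistic rates; a tail of other-origin names accompanies non-Australian
# country of birth.

.pl_surnames <- c(
  "SMITH", "JONES", "WILLIAMS", "BROWN", "WILSON", "TAYLOR", "JOHNSON",
  "WHITE", "MARTIN", "ANDERSON", "THOMPSON", "NGUYEN", "THOMAS", "WALKER",
  "HARRIS", "LEE", "RYAN", "ROBINSON", "KELLY", "KING", "DAVIS", "WRIGHT",
  "EVANS", "ROBERTS", "GREEN", "HALL", "WOOD", "JACKSON", "CLARKE", "CLARK",
  "SMYTH", "PATEL", "ALLEN", "SCOTT", "MITCHELL", "STEWART", "MOORE",
  "TURNER", "HILL", "COOPER", "WARD", "MORRIS", "GRAY", "GREY", "HUGHES",
  "MURPHY", "OBRIEN", "OCONNOR", "REID", "READ", "BAKER", "CAMPBELL",
  "COLLINS", "BELL", "MURRAY", "GRAHAM", "KENNEDY", "COOK", "BAILEY",
  "PARKER", "MILLER", "MCDONALD", "MACDONALD", "YOUNG", "PHILLIPS",
  "ADAMS", "SIMPSON", "RICHARDSON", "BARNES", "HENDERSON", "STEVENS",
  "STEPHENS", "WATSON", "GRANT", "WEBB", "PEARCE", "PIERCE", "CHAPMAN",
  "LAWSON", "HOLMES", "MASON", "HUNT", "BLACK", "PALMER", "GIBSON",
  "SHAW", "MILLS", "BUTLER", "FISHER", "FORD", "HAMILTON", "WALLACE",
  "WELLS", "WEST", "DIXON", "HUNTER", "KNIGHT", "MARSHALL", "PORTER",
  "REYNOLDS", "CHEN", "WANG", "LIU", "ZHANG", "SINGH", "KAUR", "KUMAR",
  "TRAN", "PHAM", "HOANG", "ROSSI", "RUSSO", "FERRARI", "PAPADOPOULOS",
  "GEORGIOU", "IVANOV", "NOVAK", "SILVA", "SANTOS", "FERNANDEZ", "GARCIA",
  "LOPEZ", "MULLER", "SCHMIDT", "WEBER", "HANSEN", "JENSEN", "VANDERBERG",
  "DEJONG", "KIM", "PARK", "CHOI", "YAMAMOTO", "SATO", "ALI", "KHAN",
  "HUSSAIN", "AHMED", "HASSAN", "ABDULLAH"
)
.pl_surname_wt <- c(rep(8, 11), 6, rep(5, 20), rep(3, 35), rep(2, 33),
                    rep(1, length(.pl_surnames) - 100))

.pl_given_f <- c(
  "SARAH", "EMMA", "JESSICA", "REBECCA", "MICHELLE", "LISA", "KATE",
  "KATIE", "CATHERINE", "KATHERINE", "NICOLE", "AMANDA", "MELISSA",
  "RACHEL", "RACHAEL", "LAUREN", "EMILY", "HANNAH", "CLAIRE", "CLARE",
  "SOPHIE", "CHLOE", "GEORGIA", "OLIVIA", "NATALIE", "KIRSTEN", "KRISTEN",
  "ANNA", "ANNE", "ANN", "JOANNE", "JOANNA", "HELEN", "ELLEN", "MARY",
  "MARIA", "KAREN", "SUSAN", "SUZANNE", "JENNIFER", "JENNY", "FIONA",
  "LOUISE", "ALISON", "ALLISON", "CAROLYN", "CAROLINE", "MEGAN", "MEAGAN",
  "SAMANTHA", "KYLIE", "TANYA", "TANIA", "BELINDA", "DANIELLE", "NATASHA",
  "LINH", "MAI", "PRIYA", "ANITA", "MEI", "WEI", "FATIMA", "AISHA",
  "ELENA", "SOFIA", "INGRID", "YUKI"
)
.pl_given_m <- c(
  "JAMES", "JACK", "WILLIAM", "THOMAS", "TOM", "JOSHUA", "LACHLAN",
  "SAMUEL", "SAM", "BENJAMIN", "BEN", "MATTHEW", "MATHEW", "DANIEL",
  "LUKE", "RYAN", "JACOB", "LIAM", "ETHAN", "NICHOLAS", "NICOLAS",
  "ALEXANDER", "ALEX", "MICHAEL", "CHRISTOPHER", "KRISTOPHER", "ANDREW",
  "ROBERT", "RUPERT", "DAVID", "PETER", "PAUL", "MARK", "MARC", "SIMON",
  "STEPHEN", "STEVEN", "PHILIP", "PHILLIP", "GEOFFREY", "JEFFREY",
  "HENRY", "HARRY", "OLIVER", "CHARLES", "GEORGE", "EDWARD", "PATRICK",
  "SEAN", "SHAUN", "MINH", "DUC", "RAJ", "ARJUN", "JUN", "HIRO", "OMAR",
  "YOUSSEF", "STEFAN", "MARCO", "ANDREI", "LARS"
)

.pl_streets <- c(
  "HIGH", "STATION", "CHURCH", "PARK", "VICTORIA", "GEORGE", "KING",
  "QUEEN", "ELIZABETH", "MAIN", "BEACH", "RAILWAY", "FOREST", "RIVER",
  "HILL", "SHORT", "LONG", "GARDEN", "MARKET", "BRIDGE", "CASTLE",
  "CHAPEL", "MILL", "SPRING", "SUNSET", "WATTLE", "BANKSIA", "ACACIA",
  "EUCALYPT", "JACARANDA", "KOOKABURRA", "WARATAH", "BORONIA", "GREVILLEA"
)
.pl_street_types <- c("ST", "RD", "AVE", "PDE", "CRES", "PL", "DR")
.pl_suburbs <- c(
  "NEWTOWN", "RICHMOND", "EPPING", "PENRITH", "LIVERPOOL", "PARRAMATTA",
  "BANKSTOWN", "HORNSBY", "GOSFORD", "WOLLONGONG", "NEWCASTLE", "DUBBO",
  "ORANGE", "BATHURST", "WAGGA WAGGA", "ALBURY", "TAMWORTH", "ARMIDALE",
  "GRAFTON", "LISMORE", "COFFS HARBOUR", "PORT MACQUARIE", "TAREE",
  "NOWRA", "GOULBURN", "QUEANBEYAN", "BROKEN HILL", "GRIFFITH",
  "MAITLAND", "CESSNOCK", "KATOOMBA", "CAMDEN", "CAMPBELLTOWN",
  "SUTHERLAND", "MANLY", "RANDWICK", "ASHFIELD", "BURWOOD", "RYDE",
  "BLACKTOWN"
)
.pl_countries <- c(
  "ENGLAND", "NEW ZEALAND", "CHINA", "VIETNAM", "INDIA", "PHILIPPINES",
  "ITALY", "GREECE", "LEBANON", "SOUTH AFRICA", "FIJI", "SOUTH KOREA",
  "GERMANY", "NETHERLANDS", "IRELAND", "SCOTLAND", "INDONESIA",
  "MALAYSIA", "THAILAND", "EGYPT"
)

.pl_sample <- function(pool, n, wt = NULL) {
  if (is.null(wt)) sample(pool, n, replace = TRUE)
  else sample(pool, n, replace = TRUE, prob = wt)
}

.pl_new_address <- function(n) {
  paste(
    sample(1:399, n, replace = TRUE),
    .pl_sample(.pl_streets, n),
    .pl_sample(.pl_street_types, n),
    .pl_sample(.pl_suburbs, n)
  )
}
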