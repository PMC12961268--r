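verbatim,canonical
SEMAGLUTIDE,semaglutide
OZEMPIC,semaglutide
WEGOVY,semaglutide
RYBELSUS,semaglutide
NN9535,semaglutide
LIRAGLUTIDE,liraglutide
VICTOZA,liraglutide
SAXENDA,liraglutide
NN2211,liraglutide
DULAGLUTIDE,dulaglutide
TRULICITY,dulaglutide
LY2189265,dulaglutide
EXENATIDE,exenatide
BYETTA,exenatide
BYDUREON,exenatide
AC2993,exenatide
LIXISENATIDE,lixisenatide
ADLYXIN,lixisenatide
LYXUMIA,lixisenatide
AVE0010,lixisenatide
ALBIGLUTIDE,albiglutide
TANZEUM,albiglutide
EPERZAN,albiglutide
GSK716155,albiglutide
TIRZEPATIDE,tirzepatide
MOUNJARO,tirzepatide
ZEPBOUND,tirzepatide
LY3298176,tirzepatide
LOXENATIDE,loxenatide
POLYETHYLENE GLYCOL LOXENATIDE,loxenatide
PEX168,loxenatide
PEX-168,loxenatide
METFORMIN,metformin
METFORMIN HYDROCHLORIDE,metformin
METFORMIN HCL,metformin
GLUCOPHAGE,metformin
FORTAMET,metformin
GLUMETZA,metformin
RIOMET,metformin
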