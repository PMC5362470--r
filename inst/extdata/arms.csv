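article_id,arm_id,subtrial,treatment,n_enrolled
peng2013,peng2013.TACE+RFA,1,TACE+RFA,94
peng2013,peng2013.RFA,1,RFA,95
muhammad2013,muhammad2013.TACE+SOR,1,TACE+SOR,13
muhammad2013,muhammad2013.TACE,1,TACE,30
bai2013,bai2013.TACE+SOR,1,TACE+SOR,82
bai2013,bai2013.TACE,1,TACE,164
nicolini2013,nicolini2013.DEB-TACE,1,DEB-TACE,22
nicolini2013,nicolini2013.TACE,1,TACE,16
morenoluna2013,morenoluna2013.TARE-90Y,1,TARE-90Y,61
morenoluna2013,morenoluna2013.TACE,1,TACE,55
qu2012,qu2012.TACE+SOR,1,TACE+SOR,45
qu2012,qu2012.TACE,1,TACE,45
song2012,song2012.DEB-TACE,1,DEB-TACE,60
song2012,song2012.TACE,1,TACE,69
recchia2012,recchia2012.DEB-TACE,1,DEB-TACE,35
recchia2012,recchia2012.TACE,1,TACE,70
peng2011,peng2011.TACE+RFA,1,TACE+RFA,69
peng2011,peng2011.RFA,1,RFA,70
kudo2011,kudo2011.TACE+SOR,1,TACE+SOR,229
kudo2011,kudo2011.TACE,1,TACE,229
song2011,song2011.DEB-TACE,1,DEB-TACE,20
song2011,song2011.TACE,1,TACE,20
salem2011,salem2011.TARE-90Y,1,TARE-90Y,123
salem2011,salem2011.TACE,1,TACE,122
wiggerman2011,wiggerman2011.DEB-TACE,1,DEB-TACE,22
wiggerman2011,wiggerman2011.TACE,1,TACE,22
sacco2011,sacco2011.DEB-TACE,1,DEB-TACE,33
sacco2011,sacco2011.TACE,1,TACE,34
malagari2011,malagari2011.DEB-TACE,1,DEB-TACE,41
malagari2011,malagari2011.TACE,1,TACE,43
kim2010,kim2010.TACE+RFA,1,TACE+RFA,83
kim2010,kim2010.RFA,1,RFA,231
morimoto2010,morimoto2010.TACE+RFA,1,TACE+RFA,19
morimoto2010,morimoto2010.RFA,1,RFA,18
li2010,li2010.TACE+HIFU,1,TACE+HIFU,44
li2010,li2010.TACE,1,TACE,45
tan2010,tan2010.TACE+SOR,1,TACE+SOR,10
tan2010,tan2010.TACE,1,TACE,10
kooby2010,kooby2010.TARE-90Y,1,TARE-90Y,27
kooby2010,kooby2010.TACE,1,TACE,44
carr2010,carr2010.TARE-90Y,1,TARE-90Y,99
carr2010,carr2010.TACE,1,TACE,691
ferrerpuchol2010,ferrerpuchol2010.DEB-TACE,1,DEB-TACE,47
ferrerpuchol2010,ferrerpuchol2010.TACE,1,TACE,25
dhanasekaran2010,dhanasekaran2010.DEB-TACE,1,DEB-TACE,45
dhanasekaran2010,dhanasekaran2010.TACE,1,TACE,26
shibata2009,shibata2009.TACE+RFA,1,TACE+RFA,46
shibata2009,shibata2009.TACE,1,TACE,43
yang2009,yang2009.TACE+RFA,1,TACE+RFA,31
yang2009,yang2009.RFA,1,RFA,37
yang2009,yang2009.TACE,1,TACE,35
cheng2008,cheng2008.TACE+RFA,1,TACE+RFA,96
cheng2008,cheng2008.RFA,1,RFA,100
cheng2008,cheng2008.TACE,1,TACE,95
brunello2008,brunello2008.RFA,1,RFA,70
brunello2008,brunello2008.PEI,1,PEI,69
wu2005,wu2005.TACE+HIFU,1,TACE+HIFU,24
wu2005,wu2005.TACE,1,TACE,26
becker2005,becker2005.TACE+PEI,1,TACE+PEI,27
becker2005,becker2005.TACE,1,TACE,25
shiina2005,shiina2005.RFA,1,RFA,118
shiina2005,shiina2005.PEI,1,PEI,114
lin2005,lin2005.PAI,1,PAI,63
lin2005,lin2005.PEI,1,PEI,62
shim2005,shim2005.TACE+RT,1,TACE+RT,38
shim2005,shim2005.TACE,1,TACE,35
lin2004,lin2004.RFA.1,1,RFA,50
lin2004,lin2004.PEI.1,1,PEI,46
lin2004,lin2004.RFA.2,2,RFA,50
lin2004,lin2004.PEI.2,2,PEI,50
zeng2004,zeng2004.TACE+EBRT,1,TACE+EBRT,54
zeng2004,zeng2004.TACE,1,TACE,149
lencioni2003,lencioni2003.RFA,1,RFA,52
lencioni2003,lencioni2003.PEI,1,PEI,50
guo2003,guo2003.TACE+RT,1,TACE+RT,76
guo2003,guo2003.TACE,1,TACE,89
kamada2002,kamada2002.TACE+PEI,1,TACE+PEI,32
kamada2002,kamada2002.TACE,1,TACE,37
koda2001,koda2001.TACE+PEI,1,TACE+PEI,26
koda2001,koda2001.PEI,1,PEI,26
cheng2001,cheng2001.TACE+RT,1,TACE+RT,17
cheng2001,cheng2001.RT,1,RT,9
cheng2001,cheng2001.TACE,1,TACE,16
allgaier1998,allgaier1998.TACE+PEI,1,TACE+PEI,39
allgaier1998,allgaier1998.PEI,1,PEI,15
allgaier1998,allgaier1998.TACE,1,TACE,33
bartolozzi1995,bartolozzi1995.TACE+PEI,1,TACE+PEI,26
bartolozzi1995,bartolozzi1995.TACE,1,TACE,27
kato1994,kato1994.TACE+PEI,1,TACE+PEI,24
kato1994,kato1994.TACE,1,TACE,22
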