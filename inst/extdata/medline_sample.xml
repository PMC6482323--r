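<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>26000001</PMID>
      <Article>
        <ArticleTitle>Apoptotic priming in small cell lung cancer models.</ArticleTitle>
        <Abstract>
          <AbstractText>Single agent activity was limited in resistant lines. Treatment response improved when cells were exposed to the combination of ABT-737 and paclitaxel over three cycles. The difference was reported as P≤0.001 in the primary analysis.</AbstractText>
        </Abstract>
        <Language>eng</Language>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>26000002</PMID>
      <Article>
        <ArticleTitle>Imatinib maintenance in gastrointestinal stromal tumor.</ArticleTitle>
        <Abstract>
          <AbstractText Label="BACKGROUND">Maintenance schedules vary across centers.</AbstractText>
          <AbstractText Label="METHODS">Records of imatinib dosing were reviewed retrospectively.</AbstractText>
          <AbstractText Label="RESULTS">Continuous dosing was associated with longer progression free intervals.</AbstractText>
        </Abstract>
        <Language>eng</Language>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>26000003</PMID>
      <Article>
        <ArticleTitle>Erratum to: dose banding of carboplatin in adult oncology.</ArticleTitle>
        <Language>eng</Language>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
</PubmedArticleSet>
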